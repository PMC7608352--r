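# Default phenotyping codebook (documented stand-in).
#
# The study-specific supplementary code lists are not redistributed; this
# default captures the structure of the classification cascade with
# representative ICD-9 / ICD-10 / OPCS-4 / self-report codes.  Patterns are
# "SYSTEM:code" with an optional trailing "*" for prefix match.  Each set
# that the synthetic generator emits from contains at least one exact
# (non-wildcard) code.
sets:
  # Syndromes with possible links to cardiovascular defects; dominates all
  # other rules.
  syndrome_exclusions:
    - "ICD10:Q87*"
    - "ICD10:Q871"
    - "ICD10:Q90*"
    - "ICD10:Q909"
    - "ICD10:Q91*"
    - "ICD10:Q93*"
    - "ICD10:Q96*"
    - "ICD9:758*"

  # Congenital malformations of the circulatory system (primary inclusion).
  congenital_circulatory:
    - "ICD10:Q2*"
    - "ICD10:Q210"
    - "ICD10:Q211"
    - "ICD10:Q213"
    - "ICD10:Q250"
    - "ICD10:Q251"
    - "ICD9:745*"
    - "ICD9:746*"
    - "ICD9:747*"
    - "ICD9:7454"

  # ICD-10 Q211 is ambiguous between atrial septal defect and patent
  # foramen ovale; singled out for the PFO disambiguation rules.
  q211:
    - "ICD10:Q211"

  # PFO-specific operation code.
  pfo_ops:
    - "OPCS4:K165"

  stroke:
    - "ICD10:I63*"
    - "ICD10:I639"
    - "ICD10:I64"
    - "ICD9:434*"
    - "ICD9:436"

  atrial_fibrillation:
    - "ICD10:I48*"
    - "ICD10:I489"
    - "ICD9:4273"

  # Operations commonly associated with congenital heart defects.
  cvm_ops:
    - "OPCS4:K04*"
    - "OPCS4:K041"
    - "OPCS4:K09*"
    - "OPCS4:K091"
    - "OPCS4:L05*"
    - "OPCS4:L051"

  # Self-reported congenital heart illness.
  self_report_cvm:
    - "SELF_ILLNESS:1076"

  # Self-reported heart surgery; the cascade additionally requires
  # age at operation < 18 years.
  self_report_heart_surgery:
    - "SELF_OPERATION:1095"

  # Aortic stenosis / insufficiency / valve replacement: evidence of
  # congenital bicuspid aortic valve when diagnosed before 65.
  bav_codes:
    - "ICD10:I35*"
    - "ICD10:I350"
    - "ICD10:I351"
    - "OPCS4:K26*"
    - "OPCS4:K261"
    - "SELF_ILLNESS:1490"
    - "SELF_OPERATION:1096"

  # Conditions that can cause non-congenital valve defects.
  bav_exclusions:
    - "ICD10:I33*"
    - "ICD10:I330"
    - "ICD10:I39*"
    - "ICD9:421*"

  # Acquired heart defects etc. that exclude a sample from the control set.
  control_exclusions:
    - "ICD10:I05*"
    - "ICD10:I06*"
    - "ICD10:I07*"
    - "ICD10:I08*"
    - "ICD10:I09*"
    - "ICD10:I34*"
    - "ICD10:I340"
    - "ICD10:I36*"
    - "ICD10:I37*"

  # Neuropsychiatric case set: schizophrenia spectrum, bipolar, autism,
  # intellectual disability, developmental disorders.
  neuropsych_cases:
    - "ICD10:F2*"
    - "ICD10:F200"
    - "ICD10:F250"
    - "ICD10:F30*"
    - "ICD10:F31*"
    - "ICD10:F310"
    - "ICD10:F7*"
    - "ICD10:F700"
    - "ICD10:F8*"
    - "ICD10:F800"
    - "ICD10:F810"
    - "ICD10:F840"

  # Any other mental-and-behavioural code removes a sample from the
  # neuropsychiatric control group (case set takes precedence).
  neuropsych_control_exclusions:
    - "ICD10:F*"
    - "ICD10:F329"
    - "ICD10:F419"

  # Diagnoses previously associated with the deletion, removed from the
  # whole cohort before cognitive analyses.
  cognitive_exclusions:
    - "ICD10:F2*"
    - "ICD10:F200"
    - "ICD10:F30*"
    - "ICD10:F31*"
    - "ICD10:F7*"
    - "ICD10:F8*"
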