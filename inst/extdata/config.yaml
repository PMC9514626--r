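mdd_codes:
- F32.0
- F32.1
- F32.2
- F32.3
- F32.8
- F32.9
- F33.0
- F33.1
- F33.2
- F33.3
- F33.4
- F33.8
- F33.9
severity_map:
  mild:
  - F32.0
  - F32.8
  - F32.9
  - F33.0
  - F33.4
  - F33.8
  - F33.9
  moderate:
  - F32.1
  - F33.1
  severe:
  - F32.2
  - F32.3
  - F33.2
  - F33.3
exclusion_codes:
  icd10:
  - F30
  - F31
  - F38
  - F39
  - F34
  - F20
  - F21
  - F22
  - F23
  - F24
  - F25
  - F28
  - F29
  - F00
  - F01
  - F02
  - F03
  - G30
  - R54.9
  icd8:
  - '296.19'
  - '296.39'
  - '296.89'
  - '296.99'
  - '298.19'
  - 295.x9
  - 297.x9
  - '298.29'
  - '298.39'
  - '298.49'
  - '298.59'
  - '298.69'
  - '298.79'
  - '298.89'
  - '298.99'
  - '299.04'
  - '299.05'
  - '299.09'
  - 290.x
antidepressant_class_prefixes:
  SSRI: N06AB
  SNRI: N06AX
  TCA: N06AA
  MAOI:
  - N06AF
  - N06AG
ect_codes:
- BRTB1
- BRXA1
medicine_cost_groups:
  antidepressant: N06A
  other_psychiatric:
  - N05A
  - N05B
fixed_price_table:
  sector:
  - psychiatric
  - psychiatric
  - psychiatric
  - psychiatric
  - psychiatric
  - somatic
  - somatic
  - somatic
  - somatic
  - primary
  - primary
  - primary
  - primary
  contact_type:
  - hospitalization
  - hospitalization
  - ed
  - outpatient
  - home_visit
  - hospitalization
  - hospitalization
  - ed
  - outpatient
  - gp
  - private_psychiatrist
  - private_psychologist
  - other_specialist
  admission_mode:
  - acute
  - elective
  - na
  - na
  - na
  - acute
  - elective
  - na
  - na
  - na
  - na
  - na
  - na
  price_eur:
  - 600.0
  - 550.0
  - 300.0
  - 250.0
  - 150.0
  - 800.0
  - 750.0
  - 350.0
  - 300.0
  - 25.0
  - 90.0
  - 70.0
  - 60.0
dkk_per_eur: 7.47
window_days: 365
activity_window_days: 90
study_years:
- 1996
- 2015
age_group_breaks:
- 18
- 25
- 45
- 65
- 85
age_group_labels:
- 18-24
- 25-44
- 45-64
- 65-84
- 85+
year_group_breaks:
- 1996
- 2001
- 2006
- 2011
year_group_labels:
- 1996-2000
- 2001-2005
- 2006-2010
- 2011-2015
re_initiation_counts: no
ect_always_shift: no
min_days_between_shifts: 0
cost_mode: recorded
include_index_day_in_post: no
adjust_part1: no
cluster_by_set: no
allow_partial: yes
condition_pre_window: no
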