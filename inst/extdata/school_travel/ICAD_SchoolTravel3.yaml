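name: ICAD_SchoolTravel3
description: Duration of journey to school
target_categories:
- Less than or equal to 5 min
- 6–15 min
- More than 15 min
- Missing
rules:
- study_id: SPEEDY
  wave: 1
  kind: threshold_bin
  bins:
  - upper: 5.0
    label: Less than or equal to 5 min
  - upper: 15.0
    label: 6–15 min
  - upper: ~
    label: More than 15 min
  mode_gate:
    variable: W1_school_travel
    select:
      On foot: W1_a2actmins_clean
      Bicycle: W1_a3actmins_clean
- study_id: KISS
  wave: 1
  kind: threshold_bin
  source_variable: a_schulweg_hin_sommer_time
  bins:
  - upper: 5.0
    label: Less than or equal to 5 min
  - upper: 15.0
    label: 6–15 min
  - upper: ~
    label: More than 15 min
- study_id: Ballabeina
  wave: 1
  kind: exclusion
  reason: Source duration categories (<10, 10-20, >20 min) capture different boundaries
    to the harmonised categories and could not be suitably collapsed or otherwise
    matched.
variable_group: School_travel
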