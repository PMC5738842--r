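name: ICAD_SchoolTravel2
description: Mode of travel to school (active vs other)
target_categories:
- Active mode of travel
- Other mode of travel
- Missing
rules:
- study_id: SPEEDY
  wave: 1
  kind: category_map
  source_variable: W1_school_travel
  mapping:
    Bicycle: Active mode of travel
    On foot: Active mode of travel
    Car: Other mode of travel
    Bus/train: Other mode of travel
  unmapped_policy: error
- study_id: KISS
  wave: 1
  kind: category_map
  source_variable: a_schulweg_hin_sommer
  mapping:
    Walk: Active mode of travel
    Cycle/scooter: Active mode of travel
    Car: Other mode of travel
    Bus/train/tram: Other mode of travel
  unmapped_policy: error
- study_id: Ballabeina
  wave: 1
  kind: category_map
  source_variable: W1_a_schulweg
  mapping:
    Walk: Active mode of travel
    Cycle/scooter: Active mode of travel
    Bus/tram: Other mode of travel
    Car: Other mode of travel
    Other: Other mode of travel
  unmapped_policy: error
variable_group: School_travel
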