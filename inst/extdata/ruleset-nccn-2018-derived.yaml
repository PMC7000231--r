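# Family-history criteria for genetic-evaluation referral, derived from the
# 2018 NCCN guidelines for hereditary breast/ovarian (HBOC) and
# colorectal (Lynch) cancer risk. Age thresholds are inclusive
# ("diagnosed at or before T"). The engine is criteria-agnostic: edit or
# replace this file to localize the guideline.
version: nccn-2018-derived
criteria:
  - criterion_id: B1
    disease_track: breast_ovarian
    categories: [breast]
    min_relatives: 1
    allowed_degrees: [1, 2]
    max_onset_age: 45
    min_onset_qualifying: 1
  - criterion_id: B2
    disease_track: breast_ovarian
    categories: [ovarian]
    min_relatives: 1
    allowed_degrees: [1, 2]
  - criterion_id: B3
    disease_track: breast_ovarian
    categories: [breast]
    min_relatives: 1
    allowed_degrees: [1, 2]
    relative_sex: male
  - criterion_id: B4
    disease_track: breast_ovarian
    categories: [breast]
    min_relatives: 2
    allowed_degrees: [1, 2, 3]
    max_onset_age: 50
    min_onset_qualifying: 1
    same_lineage_required: true
  - criterion_id: B5
    disease_track: breast_ovarian
    categories: [breast]
    min_relatives: 3
    allowed_degrees: [1, 2, 3]
    same_lineage_required: true
  # Ashkenazi-ancestry criterion: disabled until the site maps religion
  # codes (or another source) to ancestry flags.
  - criterion_id: B6
    disease_track: breast_ovarian
    categories: [breast]
    min_relatives: 1
    allowed_degrees: [1, 2]
    ancestry_required: ashkenazi_jewish
    enabled: false
  - criterion_id: C1
    disease_track: colorectal
    categories: [colorectal]
    min_relatives: 1
    allowed_degrees: [1]
    max_onset_age: 50
    min_onset_qualifying: 1
  - criterion_id: C2
    disease_track: colorectal
    categories: [endometrial]
    min_relatives: 1
    allowed_degrees: [1]
    max_onset_age: 50
    min_onset_qualifying: 1
  - criterion_id: C3
    disease_track: colorectal
    categories: [colorectal, endometrial, other_lynch_associated]
    min_relatives: 2
    allowed_degrees: [1, 2]
    max_onset_age: 50
    min_onset_qualifying: 1
    same_lineage_required: true
  - criterion_id: C4
    disease_track: colorectal
    categories: [colorectal, endometrial, other_lynch_associated]
    min_relatives: 3
    allowed_degrees: [1, 2]
    same_lineage_required: true
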