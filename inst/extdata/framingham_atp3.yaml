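# ATP-III sex-specific point tables for 10-year hard-CHD risk (Framingham).
# Age bands are [from, to] inclusive in completed years; cholesterol and
# smoking points depend on the decade age group. risk maps total points to a
# percent; points below the first key fall in the "<1%" band (encoded 0.5),
# points above the last key take the open top band value.
version: "atp3-chd-1.0"

age_bands: [[20, 34], [35, 39], [40, 44], [45, 49], [50, 54],
            [55, 59], [60, 64], [65, 69], [70, 74], [75, 79]]
# decade groups for cholesterol/smoking points: 20-39, 40-49, 50-59, 60-69, 70-79
decades: [[20, 39], [40, 49], [50, 59], [60, 69], [70, 79]]

total_cholesterol_cuts: [160, 200, 240, 280]   # <160, 160-199, 200-239, 240-279, >=280
hdl_points: {ge60: -1, "50_59": 0, "40_49": 1, lt40: 2}
sbp_cuts: [120, 130, 140, 160]                 # <120, 120-129, 130-139, 140-159, >=160

male:
  age_points: [-9, -4, 0, 3, 6, 8, 10, 11, 12, 13]
  chol_points:       # rows: cholesterol band (low->high); cols: decade group
    - [0, 0, 0, 0, 0]
    - [4, 3, 2, 1, 0]
    - [7, 5, 3, 1, 0]
    - [9, 6, 4, 2, 1]
    - [11, 8, 5, 3, 1]
  smoker_points: [8, 5, 3, 1, 1]
  sbp_points_untreated: [0, 0, 1, 1, 2]
  sbp_points_treated:   [0, 1, 2, 2, 3]
  risk:                # total points -> 10-year risk percent
    floor_below: 0     # points < 0  -> <1% band
    below_value: 0.5
    table: {0: 1, 1: 1, 2: 1, 3: 1, 4: 1, 5: 2, 6: 2, 7: 3, 8: 4, 9: 5,
            10: 6, 11: 8, 12: 10, 13: 12, 14: 16, 15: 20, 16: 25}
    top_from: 17
    top_value: 30

female:
  age_points: [-7, -3, 0, 3, 6, 8, 10, 12, 14, 16]
  chol_points:
    - [0, 0, 0, 0, 0]
    - [4, 3, 2, 1, 1]
    - [8, 6, 4, 2, 1]
    - [11, 8, 5, 3, 2]
    - [13, 10, 7, 4, 2]
  smoker_points: [9, 7, 4, 2, 1]
  sbp_points_untreated: [0, 1, 2, 3, 4]
  sbp_points_treated:   [0, 3, 4, 5, 6]
  risk:
    floor_below: 9     # points < 9 -> <1% band
    below_value: 0.5
    table: {9: 1, 10: 1, 11: 1, 12: 1, 13: 2, 14: 2, 15: 3, 16: 4, 17: 5,
            18: 6, 19: 8, 20: 11, 21: 14, 22: 17, 23: 22, 24: 27}
    top_from: 25
    top_value: 30
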