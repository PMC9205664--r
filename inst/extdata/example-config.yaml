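# Example beescape configuration. Every key is optional; omitted keys keep
# the package defaults (shown here). Progression units run 0-100 over the
# season; distances are meters; floral values are dimensionless in [0, 1].
landscape:
  side_length_m: 2010
  cell_size_m: 10
  snh_proportion: 0.10
  snh_patch_area_m2: 10000
  bee_habitat_total: 0.60
  early_mfc_share: 0.5
  crop_patch_area_m2: 500
  nest_density: 121          # nests per km2 of SNH
phenology:
  snh:       {start: 10, end: 96, f_max: 0.34}
  early_mfc: {start: 24, end: 55, f_max: 1.0}
  late_mfc:  {start: 30, end: 62, f_max: 0.7}
progression:
  midpoint_day: 200
  scale_days: 65
foraging:
  gamma: 250                 # mean foraging dispersal distance, m
  competition: shared_cell   # or: independent
  denominator: nest          # or: target
pollination:
  kappa: 1.0
colony:
  phi: 10                    # queen emergence (progression units)
  mu: 30                     # workers take over foraging
  psi: 55                    # daughter-queen production starts
  alpha: 50                  # max production per nest per week
  beta: 5                    # production half-saturation resource scale
  delta: 0.7                 # weekly survival, stages A2-B2
  epsilon: 0.74              # worker share of stage-B2 production
  pw: 0.5                    # fraction of workers foraging
  a1_duration_weeks: 2
  b3_survival_decay: 0.8
drought:
  start_gdd: 28              # progression units; fixed early-season start
  duration_weeks: 4
  positive_growth_factor: 0.08
  negative_growth_multiplier: 1.5
weeks: {from: 1, to: 52}
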