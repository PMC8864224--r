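# Model inputs for the sintilimab + bevacizumab biosimilar vs sorafenib
# cost-effectiveness analysis (unresectable HCC, Chinese healthcare system
# perspective). Every tabulated input appears exactly once in this file.
# Ranges are 95% intervals where published as CIs, otherwise +/-20% of the
# base case; distributions are those used in the probabilistic sensitivity
# analysis (fixed = not sampled).

model:
  cycle_days: 21
  price_cycle_days: 21   # per-cycle prices refer to one q3w administration
  horizon_years: 40          # effectively lifetime for this population
  annual_discount: 0.03
  days_per_month: 30.4375
  half_cycle_correction: true
  wtp_per_qaly: 30552

# comparator-arm survival, fitted to digitized trial curves (months)
curves:
  pfs_reference: {family: lognormal,   params: {mu: 1.121355, sigma: 0.7702185}}
  os_reference:  {family: loglogistic, params: {lambda: 0.01822555, gamma: 1.694566}}

parameters:
  # clinical
  hr_pfs:            {base: 0.560, low: 0.460, high: 0.700, distribution: lognormal}
  hr_os:             {base: 0.570, low: 0.430, high: 0.750, distribution: lognormal}
  subs_prop_soraf:   {base: 0.470, low: 0.376, high: 0.564, distribution: beta}
  subs_prop_combo:   {base: 0.290, low: 0.232, high: 0.348, distribution: beta}
  # grade >=3 adverse-event incidence, sorafenib arm
  ae_inc_soraf_ast:  {base: 0.05,  low: 0.040, high: 0.060, distribution: beta}
  ae_inc_soraf_plt:  {base: 0.03,  low: 0.024, high: 0.036, distribution: beta}
  ae_inc_soraf_bili: {base: 0.03,  low: 0.024, high: 0.036, distribution: beta}
  ae_inc_soraf_htn:  {base: 0.06,  low: 0.048, high: 0.072, distribution: beta}
  ae_inc_soraf_ppe:  {base: 0.12,  low: 0.096, high: 0.144, distribution: beta}
  # grade >=3 adverse-event incidence, sintilimab + bevacizumab biosimilar arm
  ae_inc_combo_ast:  {base: 0.020, low: 0.016, high: 0.024, distribution: beta}
  ae_inc_combo_plt:  {base: 0.08,  low: 0.064, high: 0.096, distribution: beta}
  ae_inc_combo_bili: {base: 0.05,  low: 0.040, high: 0.060, distribution: beta}
  ae_inc_combo_htn:  {base: 0.14,  low: 0.112, high: 0.168, distribution: beta}
  ae_inc_combo_ppe:  {base: 0.0,   low: 0.0,   high: 0.0,   distribution: beta}
  # utilities
  u_pfd:             {base: 0.760, low: 0.610, high: 0.910, distribution: beta}
  u_pd:              {base: 0.680, low: 0.540, high: 0.820, distribution: beta}
  disutility_g12:    {base: 0.010, low: 0.008, high: 0.020, distribution: beta}
  disutility_g3:     {base: 0.160, low: 0.110, high: 0.204, distribution: beta}
  # adverse-event management cost, USD per event
  ae_cost_ast:       {base: 87,    low: 70,    high: 105,   distribution: gamma}
  ae_cost_plt:       {base: 1054,  low: 843,   high: 1265,  distribution: gamma}
  ae_cost_bili:      {base: 114,   low: 91,    high: 136,   distribution: gamma}
  ae_cost_htn:       {base: 1.35,  low: 1.08,  high: 1.62,  distribution: gamma}
  ae_cost_ppe:       {base: 34,    low: 27,    high: 40,    distribution: gamma}
  # drug and care costs, USD per 21-day cycle
  cost_sintilimab:   {base: 804,   low: 643,   high: 965,   distribution: gamma}
  cost_bevacizumab:  {base: 1465,  low: 1172,  high: 1758,  distribution: gamma}
  cost_sorafenib:    {base: 790,   low: 632,   high: 948,   distribution: gamma}
  cost_test:         {base: 352,   low: 282,   high: 423,   distribution: gamma}
  cost_pembrolizumab: {base: 5069, low: 4055,  high: 6082,  distribution: gamma}
  cost_regorafenib:  {base: 1747,  low: 1397,  high: 2096,  distribution: gamma}
  cost_bsc:          {base: 357,   low: 286,   high: 428,   distribution: gamma}

arms:
  comparator:
    name: sorafenib
    drug_costs: [cost_sorafenib]
    max_treatment_months: null        # treat to progression
    subsequent_drug: cost_pembrolizumab
    subsequent_proportion: subs_prop_soraf
    # per-patient second-line duration, calibrated (see methods vignette)
    subsequent_max_months: 7.6
    ae_incidence: [ae_inc_soraf_ast, ae_inc_soraf_plt, ae_inc_soraf_bili,
                   ae_inc_soraf_htn, ae_inc_soraf_ppe]
  intervention:
    name: sintilimab-bevacizumab
    drug_costs: [cost_sintilimab, cost_bevacizumab]
    max_treatment_months: 24          # first-line cap
    subsequent_drug: cost_regorafenib
    subsequent_proportion: subs_prop_combo
    # effectively until death, calibrated (see methods vignette)
    subsequent_max_months: 248.4
    ae_incidence: [ae_inc_combo_ast, ae_inc_combo_plt, ae_inc_combo_bili,
                   ae_inc_combo_htn, ae_inc_combo_ppe]

# shared AE cost mapping, in the same order as each arm's ae_incidence list
ae_costs: [ae_cost_ast, ae_cost_plt, ae_cost_bili, ae_cost_htn, ae_cost_ppe]
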