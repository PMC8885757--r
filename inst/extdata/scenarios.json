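{
  "base":   {"label": "Base Case", "include_in_averaging": true},
  "scen1":  {"label": "lognormal Rmax prior, CV 50%", "include_in_averaging": true,
             "priors": {"r_max": {"dist": "lnorm", "pars": [-2.67, 0.5]}}},
  "scen2":  {"label": "lognormal Rmax prior, CV 30%", "include_in_averaging": true,
             "priors": {"r_max": {"dist": "lnorm", "pars": [-2.67, 0.3]}}},
  "scen3":  {"label": "truncated lognormal Rmax prior", "include_in_averaging": true,
             "priors": {"r_max": {"dist": "tlnorm", "pars": [-2.67, 0.5, 0.02, 0.11]}}},
  "scen4":  {"label": "sigma2 upper bound x100", "include_in_averaging": false,
             "priors": {"sigma2": {"dist": "unif", "pars": [6.5e-5, 6.5e-3]}}},
  "scen5":  {"label": "sigma2 upper bound x2", "include_in_averaging": false,
             "priors": {"sigma2": {"dist": "unif", "pars": [6.5e-5, 1.3e-4]}}},
  "scen6":  {"label": "Nrecent anchored in 2004", "include_in_averaging": true,
             "anchor_year": 2004},
  "scen7":  {"label": "no struck-and-lost correction", "include_in_averaging": false,
             "catch_series": "no_slr"},
  "scen8":  {"label": "low catch series only", "include_in_averaging": false,
             "catch_series": "low"},
  "scen9":  {"label": "high catch series only", "include_in_averaging": false,
             "catch_series": "high"},
  "scen10": {"label": "no minimum-abundance floor", "include_in_averaging": true,
             "n_c": 0},
  "scen11": {"label": "floor from 25 haplotypes", "include_in_averaging": true,
             "n_c": 75},
  "scen12": {"label": "floor from 37 haplotypes", "include_in_averaging": true,
             "n_c": 111},
  "scen13": {"label": "estimated extra observation error", "include_in_averaging": true,
             "priors": {"tau2": {"dist": "lnorm", "pars": [-1.6094379124341003, 0.5]}}},
  "scen14": {"label": "density-dependent catchability", "include_in_averaging": true,
             "priors": {"beta": {"dist": "norm", "pars": [0, 0.1]}}}
}
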