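{
  "notes": [
    "Published base-case configuration: cost-utility of daily vitamin D",
    "supplementation (400 IU) to prevent acute respiratory infection (ARI)",
    "in school children, six-month horizon, societal perspective, 2020 USD.",
    "Probabilities carry beta uncertainty, daily costs gamma uncertainty",
    "(spread = natural-scale SD), the relative risk lognormal uncertainty",
    "(spread = SD of the log; the 0.71 median with sdlog 0.11 implies a",
    "95% interval of about 0.57-0.88)."
  ],
  "parameters": {
    "p_ari": 0.22,
    "rr_vitd": 0.71,
    "m_ari": 0.0001,
    "m_all": 0.0008,
    "du_ari": 0.06,
    "c_ari_day": 880,
    "c_vitd_day": 0.08
  },
  "distributions": {
    "p_ari": { "family": "beta", "spread": 0.005 },
    "rr_vitd": { "family": "lognormal", "spread": 0.11 },
    "m_ari": { "family": "beta", "spread": 0.000029 },
    "m_all": { "family": "beta", "spread": 0.00022 },
    "du_ari": { "family": "beta", "spread": 0.015 },
    "c_ari_day": { "family": "gamma", "spread": 222 },
    "c_vitd_day": { "family": "gamma", "spread": 0.02 }
  },
  "settings": {
    "episode_days": 10,
    "suppl_days": 182,
    "horizon_days": 182,
    "wtp": 19000,
    "scale_by_horizon": false
  }
}
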