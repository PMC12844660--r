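seed: 1
drugs:
  ceftazidime/avibactam:
    n_total: 904
    categories:
      resistance: 93.0
      ineffectiveness: 85.0
      off_label: 118.0
    demographics:
      age_group:
        NS: 155.0
        0-1 Month: 2.0
        2 Months-2 Years: 15.0
        3-11 Years: 13.0
        12-17 Years: 15.0
        18-64 Years: 348.0
        65-85 Years: 279.0
        '>85 Years': 77.0
      sex:
        Female: 295.0
        Male: 539.0
        NS: 70.0
      origin:
        EEA: 399.0
        Non-EEA: 505.0
        NS: 0.0
      reporter:
        HP: 793.0
        Non-HP: 111.0
        NS: 0.0
    outcomes:
      resistance:
        Fatal: 9.0
        NotRecovered: 1.0
      ineffectiveness:
        Fatal: 21.0
        NotRecovered: 5.0
        RecoveredWithSequelae: 1.0
      off_label:
        Fatal: 4.0
        NotRecovered: 1.0
    soc_counts:
      Hepatobiliary disorders: 73.0
  ceftaroline:
    n_total: 559
    categories:
      resistance: 24.0
      ineffectiveness: 63.0
      off_label: 118.0
    demographics:
      age_group:
        NS: 107.0
        0-1 Month: 1.0
        2 Months-2 Years: 4.0
        3-11 Years: 5.0
        12-17 Years: 18.0
        18-64 Years: 233.0
        65-85 Years: 163.0
        '>85 Years': 28.0
      sex:
        Female: 215.0
        Male: 308.0
        NS: 36.0
      origin:
        EEA: 213.0
        Non-EEA: 346.0
        NS: 0.0
      reporter:
        HP: 548.0
        Non-HP: 11.0
        NS: 0.0
    outcomes:
      resistance:
        Fatal: 2.0
        NotRecovered: 1.0
      ineffectiveness:
        Fatal: 14.0
        NotRecovered: 1.0
      off_label:
        Fatal: 1.0
        NotRecovered: 3.0
    soc_counts:
      Blood and lymphatic system disorders: 214.0
      Hepatobiliary disorders: 14.0
      Nervous system disorders: 40.0
      Renal and urinary disorders: 43.0
      Skin and subcutaneous tissue disorders: 108.0
  ceftolozane/tazobactam:
    n_total: 560
    categories:
      resistance: 24.0
      ineffectiveness: 60.0
      off_label: 154.0
    demographics:
      age_group:
        NS: 169.0
        0-1 Month: 0.0
        2 Months-2 Years: 3.0
        3-11 Years: 6.0
        12-17 Years: 10.0
        18-64 Years: 183.0
        65-85 Years: 164.0
        '>85 Years': 25.0
      sex:
        Female: 194.0
        Male: 308.0
        NS: 58.0
      origin:
        EEA: 312.0
        Non-EEA: 248.0
        NS: 0.0
      reporter:
        HP: 552.0
        Non-HP: 8.0
        NS: 0.0
    outcomes:
      resistance:
        Fatal: 3.0
        NotRecovered: 2.0
      ineffectiveness:
        Fatal: 7.0
    soc_counts:
      Hepatobiliary disorders: 21.0
      Nervous system disorders: 48.0
  cefiderocol:
    n_total: 176
    categories:
      resistance: 52.0
      ineffectiveness: 25.0
      off_label: 16.0
    demographics:
      age_group:
        NS: 21.0
        0-1 Month: 0.0
        2 Months-2 Years: 0.0
        3-11 Years: 1.0
        12-17 Years: 6.0
        18-64 Years: 86.0
        65-85 Years: 58.0
        '>85 Years': 4.0
      sex:
        Female: 71.0
        Male: 101.0
        NS: 4.0
      origin:
        EEA: 143.0
        Non-EEA: 33.0
        NS: 0.0
      reporter:
        HP: 175.0
        Non-HP: 1.0
        NS: 0.0
    outcomes:
      resistance:
        Fatal: 1.0
        NotRecovered: 2.0
      ineffectiveness:
        Fatal: 7.0
        NotRecovered: 2.0
    soc_counts:
      Hepatobiliary disorders: 18.0
  ceftobiprole:
    n_total: 146
    categories:
      resistance: 0.0
      ineffectiveness: 2.0
      off_label: 30.0
    demographics:
      age_group:
        NS: 13.0
        0-1 Month: 0.0
        2 Months-2 Years: 0.0
        3-11 Years: 0.0
        12-17 Years: 0.0
        18-64 Years: 48.0
        65-85 Years: 71.0
        '>85 Years': 14.0
      sex:
        Female: 62.0
        Male: 79.0
        NS: 5.0
      origin:
        EEA: 118.0
        Non-EEA: 28.0
        NS: 0.0
      reporter:
        HP: 146.0
        Non-HP: 0.0
        NS: 0.0
    outcomes:
      ineffectiveness:
        Fatal: 1.0
      off_label:
        NotRecovered: 2.0
    soc_counts:
      Hepatobiliary disorders: 5.0
      Nervous system disorders: 54.0
      Renal and urinary disorders: 7.0
      Skin and subcutaneous tissue disorders: 38.0
      Infections and infestations: 8.0
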