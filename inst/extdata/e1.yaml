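id: e1
populations:
- name: P
  island_group: Chichijima
  n_diploid: 14
  N_current: 50000.0
- name: G
  island_group: Chichijima
  n_diploid: 14
  N_current: 50000.0
- name: S
  island_group: Chichijima
  n_diploid: 12
  N_current: 10000.0
- name: SG
  island_group: Hahajima
  n_diploid: 13
  N_current: 50000.0
- name: SD
  island_group: Hahajima
  n_diploid: 13
  N_current: 10000.0
- name: ST
  island_group: Hahajima
  n_diploid: 7
  N_current: 20000.0
events:
- time: 14040.0
  kind: size_change
  source: P
  new_size: 300.0
- time: 14040.0
  kind: size_change
  source: G
  new_size: 300.0
- time: 14040.0
  kind: size_change
  source: SG
  new_size: 300.0
- time: 14040.0
  kind: size_change
  source: ST
  new_size: 2000.0
- time: 14580.0
  kind: divergence
  source: G
  sink: P
- time: 14840.0
  kind: divergence
  source: S
  sink: P
- time: 15100.0
  kind: divergence
  source: SG
  sink: P
- time: 15380.0
  kind: divergence
  source: SD
  sink: P
- time: 34140.0
  kind: divergence
  source: ST
  sink: P
- time: 34140.0
  kind: size_change
  source: P
  new_size: 10000.0
mu: 1.74e-08
migration:
  t_end: 14040.0
  rates:
  - from: P
    to: G
    rate: 2.0e-06
  - from: G
    to: S
    rate: 1.0e-05
  - from: S
    to: P
    rate: 2.0e-06
  - from: SG
    to: SD
    rate: 1.0e-05
  - from: SD
    to: ST
    rate: 5.0e-06
  - from: ST
    to: SG
    rate: 2.0e-06
free_params:
- name: T1
  targets: time:9
  lower: 100.0
  upper: 100000.0
- name: T2
  targets: time:8
  lower: 100.0
  upper: 100000.0
- name: T3
  targets: time:7
  lower: 100.0
  upper: 100000.0
- name: T4
  targets: time:6
  lower: 100.0
  upper: 100000.0
- name: T5
  targets: time:5
  lower: 100.0
  upper: 100000.0
- name: T_exp
  targets: time:1;time:2;time:3;time:4
  lower: 100.0
  upper: 100000.0
- name: N_P
  targets: N:P
  lower: 100.0
  upper: 1000000.0
- name: N_G
  targets: N:G
  lower: 100.0
  upper: 1000000.0
- name: N_S
  targets: N:S
  lower: 100.0
  upper: 1000000.0
- name: N_SG
  targets: N:SG
  lower: 100.0
  upper: 1000000.0
- name: N_SD
  targets: N:SD
  lower: 100.0
  upper: 1000000.0
- name: N_ST
  targets: N:ST
  lower: 100.0
  upper: 1000000.0
- name: Nexp_P
  targets: size:1
  lower: 100.0
  upper: 1000000.0
- name: Nexp_G
  targets: size:2
  lower: 100.0
  upper: 1000000.0
- name: Nexp_SG
  targets: size:3
  lower: 100.0
  upper: 1000000.0
- name: Nexp_ST
  targets: size:4
  lower: 100.0
  upper: 1000000.0
- name: Nanc
  targets: size:10
  lower: 100.0
  upper: 1000000.0
- name: m_P_G
  targets: mig:P:G
  lower: 1.0e-08
  upper: 0.1
- name: m_G_S
  targets: mig:G:S
  lower: 1.0e-08
  upper: 0.1
- name: m_S_P
  targets: mig:S:P
  lower: 1.0e-08
  upper: 0.1
- name: m_SG_SD
  targets: mig:SG:SD
  lower: 1.0e-08
  upper: 0.1
- name: m_SD_ST
  targets: mig:SD:ST
  lower: 1.0e-08
  upper: 0.1
- name: m_ST_SG
  targets: mig:ST:SG
  lower: 1.0e-08
  upper: 0.1
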