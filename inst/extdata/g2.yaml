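id: g2
populations:
- name: S
  island_group: Chichijima
  n_diploid: 12
  N_current: 8000.0
- name: Sm
  island_group: Mukojima
  n_diploid: 7
  N_current: 3000.0
- name: STm
  island_group: Mukojima
  n_diploid: 7
  N_current: 3000.0
- name: ST
  island_group: Hahajima
  n_diploid: 7
  N_current: 20000.0
- name: SG
  island_group: Hahajima
  n_diploid: 13
  N_current: 50000.0
events:
- time: 7420.0
  kind: size_change
  source: S
  new_size: 20000.0
- time: 7420.0
  kind: size_change
  source: Sm
  new_size: 310000.0
- time: 7420.0
  kind: size_change
  source: STm
  new_size: 310000.0
- time: 14040.0
  kind: size_change
  source: SG
  new_size: 2000.0
- time: 14040.0
  kind: size_change
  source: ST
  new_size: 2000.0
- time: 16280.0
  kind: divergence
  source: Sm
  sink: S
- time: 16460.0
  kind: divergence
  source: STm
  sink: ST
- time: 17200.0
  kind: divergence
  source: SG
  sink: S
- time: 33760.0
  kind: divergence
  source: ST
  sink: S
- time: 33760.0
  kind: size_change
  source: S
  new_size: 10000.0
mu: 1.74e-08
migration:
  t_end: 7420.0
  rates:
  - from: Sm
    to: STm
    rate: 3.3333333e-05
  - from: STm
    to: Sm
    rate: 3.3333333e-05
  - from: ST
    to: SG
    rate: 2.0e-06
  - from: SG
    to: ST
    rate: 5.0e-06
free_params:
- name: T2
  targets: time:6
  lower: 100.0
  upper: 100000.0
- name: T3
  targets: time:7
  lower: 100.0
  upper: 100000.0
- name: T_SG
  targets: time:8
  lower: 100.0
  upper: 100000.0
- name: T1
  targets: time:9
  lower: 100.0
  upper: 100000.0
- name: T_red
  targets: time:1;time:2;time:3
  lower: 100.0
  upper: 100000.0
- name: T_exp
  targets: time:4;time:5
  lower: 100.0
  upper: 100000.0
- name: N_S
  targets: N:S
  lower: 100.0
  upper: 1000000.0
- name: N_Sm
  targets: N:Sm
  lower: 100.0
  upper: 1000000.0
- name: N_STm
  targets: N:STm
  lower: 100.0
  upper: 1000000.0
- name: N_ST
  targets: N:ST
  lower: 100.0
  upper: 1000000.0
- name: N_SG
  targets: N:SG
  lower: 100.0
  upper: 1000000.0
- name: Nred_S
  targets: size:1
  lower: 100.0
  upper: 1000000.0
- name: Nred_Sm
  targets: size:2
  lower: 100.0
  upper: 1000000.0
- name: Nred_STm
  targets: size:3
  lower: 100.0
  upper: 1000000.0
- name: Nexp_SG
  targets: size:4
  lower: 100.0
  upper: 1000000.0
- name: Nexp_ST
  targets: size:5
  lower: 100.0
  upper: 1000000.0
- name: Nanc
  targets: size:10
  lower: 100.0
  upper: 1000000.0
- name: m_Sm_STm
  targets: mig:Sm:STm
  lower: 1.0e-08
  upper: 0.1
- name: m_STm_Sm
  targets: mig:STm:Sm
  lower: 1.0e-08
  upper: 0.1
- name: m_SG_ST
  targets: mig:SG:ST
  lower: 1.0e-08
  upper: 0.1
- name: m_ST_SG
  targets: mig:ST:SG
  lower: 1.0e-08
  upper: 0.1
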