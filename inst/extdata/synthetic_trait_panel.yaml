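- trait_id: SU01
  n_stages: 2
  bilateral: no
  block: sutures
  lambda: 0.6
- trait_id: SU02
  n_stages: 2
  bilateral: no
  block: sutures
  lambda: 0.6
- trait_id: SU03
  n_stages: 2
  bilateral: no
  block: sutures
  lambda: 0.6
- trait_id: SU04
  n_stages: 2
  bilateral: no
  block: sutures
  lambda: 0.6
- trait_id: SU05
  n_stages: 2
  bilateral: no
  block: sutures
  lambda: 0.6
- trait_id: SU06
  n_stages: 2
  bilateral: no
  block: sutures
  lambda: 0.6
- trait_id: SU07
  n_stages: 2
  bilateral: no
  block: sutures
  lambda: 0.6
- trait_id: SU08
  n_stages: 2
  bilateral: no
  block: sutures
  lambda: 0.6
- trait_id: SU09
  n_stages: 2
  bilateral: no
  block: sutures
  lambda: 0.6
- trait_id: VX01
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX02
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX03
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX04
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX05
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX06
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX07
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX08
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX09
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX10
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX11
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX12
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX13
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX14
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX15
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: VX16
  n_stages: 3
  bilateral: no
  block: axial
  lambda: 2.2
- trait_id: AP01
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 0.9
- trait_id: AP02
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 1.8
- trait_id: AP03
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 0.9
- trait_id: AP04
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 1.8
- trait_id: AP05
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 0.9
- trait_id: AP06
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 1.8
- trait_id: AP07
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 0.9
- trait_id: AP08
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 1.8
- trait_id: AP09
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 0.9
- trait_id: AP10
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 1.8
- trait_id: AP11
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 0.9
- trait_id: AP12
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 1.8
- trait_id: AP13
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 0.9
- trait_id: AP14
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 1.8
- trait_id: AP15
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 0.9
- trait_id: AP16
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 1.8
- trait_id: AP17
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 0.9
- trait_id: AP18
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 1.8
- trait_id: AP19
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 0.9
- trait_id: AP20
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 1.8
- trait_id: AP21
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 0.9
- trait_id: AP22
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 1.8
- trait_id: AP23
  n_stages: 2
  bilateral: yes
  block: appendicular
  lambda: 0.9
- trait_id: CL01
  n_stages: 3
  bilateral: yes
  block: clavicle
  lambda: 2.0
- trait_id: CL02
  n_stages: 3
  bilateral: yes
  block: clavicle
  lambda: 2.0
- trait_id: RB01
  n_stages: 3
  bilateral: no
  block: first_rib
  lambda: 1.9
- trait_id: RB02
  n_stages: 2
  bilateral: no
  block: first_rib
  lambda: 1.9
- trait_id: PS01
  n_stages: 3
  bilateral: yes
  block: pubic_symphysis
  lambda: 1.6
- trait_id: PS02
  n_stages: 3
  bilateral: yes
  block: pubic_symphysis
  lambda: 1.6
- trait_id: PS03
  n_stages: 3
  bilateral: yes
  block: pubic_symphysis
  lambda: 1.6
- trait_id: SI01
  n_stages: 3
  bilateral: yes
  block: sacroiliac
  lambda: 1.7
- trait_id: SI02
  n_stages: 3
  bilateral: yes
  block: sacroiliac
  lambda: 1.7
- trait_id: SI03
  n_stages: 3
  bilateral: yes
  block: sacroiliac
  lambda: 1.7
- trait_id: SI04
  n_stages: 3
  bilateral: yes
  block: sacroiliac
  lambda: 1.7
- trait_id: SI05
  n_stages: 3
  bilateral: no
  block: sacroiliac
  lambda: 1.7
- trait_id: SI06
  n_stages: 2
  bilateral: no
  block: sacroiliac
  lambda: 1.7
- trait_id: AC01
  n_stages: 3
  bilateral: yes
  block: acetabulum
  lambda: 2.0
- trait_id: AC02
  n_stages: 3
  bilateral: yes
  block: acetabulum
  lambda: 2.0
- trait_id: AC03
  n_stages: 3
  bilateral: yes
  block: acetabulum
  lambda: 2.0
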