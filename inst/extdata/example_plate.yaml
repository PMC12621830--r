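vehicle_fraction: 0.001
wells:
- well: C1
  drug: vehicle
  dose: 0.0
  control_group: ctrlA
  positions: 9
- well: C2
  drug: vehicle
  dose: 0.0
  control_group: ctrlB
  positions: 9
- well: D1
  drug: drugA
  dose: 0.01
  control_group: ''
  positions: 9
- well: D2
  drug: drugA
  dose: 0.0316
  control_group: ''
  positions: 9
- well: D3
  drug: drugA
  dose: 0.1
  control_group: ''
  positions: 9
- well: D4
  drug: drugA
  dose: 0.316
  control_group: ''
  positions: 9
- well: D5
  drug: drugA
  dose: 1.0
  control_group: ''
  positions: 9
- well: D6
  drug: drugA
  dose: 3.16
  control_group: ''
  positions: 9
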