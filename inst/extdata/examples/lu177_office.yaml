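# Lu-177 DOTATATE treatment room next to an office: five 200 mCi
# administrations a week, 4 h residence each, shielding the office side to
# the US public limit of 20 uGy/week. The straight-line distance from the
# patient (point source) to the point of concern is 2.40 m.
nuclide: Lu-177
workload:
  activity_mCi: 200
  hours: 4
  sessions_per_week: 5
  apply_decay: false
distance_cm: 240
limit_uGy_per_week: 20
occupancy: office
material: lead
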