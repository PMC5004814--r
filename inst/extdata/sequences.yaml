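# Printed pulse kinematics and standard sequence sets.
# Three-pulse set: F/M/S impulses, 34-ms interpulse interval.
# Four-pulse set: same-intensity FSFS/SFFS task pulses (F4/S4).
pulses:
  F:  {label: F,  rise_ms: 8,    fall_ms: 8,    amplitude_mm: 1.03, nominal_peak_velocity_mm_s: 220}
  M:  {label: M,  rise_ms: 11,   fall_ms: 11,   amplitude_mm: 1.15, nominal_peak_velocity_mm_s: 170}
  S:  {label: S,  rise_ms: 14,   fall_ms: 14,   amplitude_mm: 1.14, nominal_peak_velocity_mm_s: 110}
  F4: {label: F4, rise_ms: 9,    fall_ms: 9,    amplitude_mm: 1.2,  nominal_peak_velocity_mm_s: 216}
  S4: {label: S4, rise_ms: 12.5, fall_ms: 12.5, amplitude_mm: 0.7,  nominal_peak_velocity_mm_s: 120}
sequences:
  - {name: FFF,  pulses: [F, F, F],      gap_ms: 34, reward_side: right}
  - {name: FMS,  pulses: [F, M, S],      gap_ms: 34, reward_side: right}
  - {name: SMF,  pulses: [S, M, F],      gap_ms: 34, reward_side: left}
  - {name: SSS,  pulses: [S, S, S],      gap_ms: 34, reward_side: left}
  - {name: FSFS, pulses: [F4, S4, F4, S4], gap_ms: 34, reward_side: right}
  - {name: SFFS, pulses: [S4, F4, F4, S4], gap_ms: 34, reward_side: left}
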