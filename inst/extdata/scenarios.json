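{
  "case1": {
    "description": "Lower seeding density: 1.5e6 cells/mL in 4%/4% gelatin/alginate bioink; only C_initial changes (2000 on the lattice scale).",
    "override": {"c_initial": 2000},
    "measurement_days": [0, 3, 7, 10],
    "qualitative": [
      "fold increases monotonically through day 10",
      "growth has not plateaued by day 7: fold(day 10) > fold(day 7)"
    ]
  },
  "case2": {
    "description": "Stiffer bioink: 4%/5% gelatin/alginate, 2e6 cells/mL; only the movement period changes (m_c = 20 h).",
    "override": {"m_c": 20},
    "measurement_days": [0, 4, 7, 11],
    "qualitative": [
      "fold trend close to the base case over 11 days",
      "per-cell displacement smaller than the base case (fewer movement events)"
    ]
  },
  "note": "Numeric in-vitro values for both cases were published only graphically in the reference study; fixtures therefore carry qualitative shape constraints, used by the validation tests."
}
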