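{
  "comment": "Mosaic-mode recipe: an 85-residue hinge target split into overlapping windows, later segments seeded from the shared anchor of the best earlier prediction, merged by anchor superposition.",
  "mode": "mosaic",
  "seed": 1,
  "n_models": 1,
  "backend": "mock",
  "chains": [
    {"chain_id": "A", "sequence": "MVVTHHQICNAEWCTDAIWKNVIYTWFYWVITFVLCEEAWIFMACTKFSLFDCVQKIRMCVMFETFHSVHIMKHHWNIMRYSNHQ"}
  ],
  "templates": [
    {"source": {"fixture": {"kind": "two_block_hinge", "hinge_angle": 25, "seed": 2, "sequence": "MVVTHHQICNAEWCTDAIWKNVIYTWFYWVITFVLCEEAWIFMACTKFSLFDCVQKIRMCVMFETFHSVHIMKHHWNIMRYSNHQ", "name": "hinge_template"}}}
  ],
  "mosaic": {"max_len": 45, "overlap": 30, "seed_policy": "best_of_previous"}
}
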