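{
  "comment": "Naive-mode recipe: eight harvested templates drawn from two conformational states of a hinge protein are clustered automatically (default two groups) and one guided branch is predicted per group.",
  "mode": "naive",
  "seed": 1,
  "n_models": 1,
  "backend": "mock",
  "chains": [
    {"chain_id": "A", "sequence": "MVVTHHQICNAEWCTDAIWKNVIYTWFYWVITFVLCEEAWIFMACTKFSLFDCVQKIRMCVMFETFHSVHIMKHHWNIMRYSNHQ"}
  ],
  "templates": [
    {"source": {"fixture": {"kind": "two_block_hinge", "hinge_angle": 0, "noise": 0.2, "seed": 131, "sequence": "MVVTHHQICNAEWCTDAIWKNVIYTWFYWVITFVLCEEAWIFMACTKFSLFDCVQKIRMCVMFETFHSVHIMKHHWNIMRYSNHQ", "name": "inward_1"}}},
    {"source": {"fixture": {"kind": "two_block_hinge", "hinge_angle": 0, "noise": 0.2, "seed": 262, "sequence": "MVVTHHQICNAEWCTDAIWKNVIYTWFYWVITFVLCEEAWIFMACTKFSLFDCVQKIRMCVMFETFHSVHIMKHHWNIMRYSNHQ", "name": "inward_2"}}},
    {"source": {"fixture": {"kind": "two_block_hinge", "hinge_angle": 0, "noise": 0.2, "seed": 393, "sequence": "MVVTHHQICNAEWCTDAIWKNVIYTWFYWVITFVLCEEAWIFMACTKFSLFDCVQKIRMCVMFETFHSVHIMKHHWNIMRYSNHQ", "name": "inward_3"}}},
    {"source": {"fixture": {"kind": "two_block_hinge", "hinge_angle": 0, "noise": 0.2, "seed": 524, "sequence": "MVVTHHQICNAEWCTDAIWKNVIYTWFYWVITFVLCEEAWIFMACTKFSLFDCVQKIRMCVMFETFHSVHIMKHHWNIMRYSNHQ", "name": "inward_4"}}},
    {"source": {"fixture": {"kind": "two_block_hinge", "hinge_angle": 30, "noise": 0.2, "seed": 655, "sequence": "MVVTHHQICNAEWCTDAIWKNVIYTWFYWVITFVLCEEAWIFMACTKFSLFDCVQKIRMCVMFETFHSVHIMKHHWNIMRYSNHQ", "name": "outward_1"}}},
    {"source": {"fixture": {"kind": "two_block_hinge", "hinge_angle": 30, "noise": 0.2, "seed": 786, "sequence": "MVVTHHQICNAEWCTDAIWKNVIYTWFYWVITFVLCEEAWIFMACTKFSLFDCVQKIRMCVMFETFHSVHIMKHHWNIMRYSNHQ", "name": "outward_2"}}},
    {"source": {"fixture": {"kind": "two_block_hinge", "hinge_angle": 30, "noise": 0.2, "seed": 917, "sequence": "MVVTHHQICNAEWCTDAIWKNVIYTWFYWVITFVLCEEAWIFMACTKFSLFDCVQKIRMCVMFETFHSVHIMKHHWNIMRYSNHQ", "name": "outward_3"}}},
    {"source": {"fixture": {"kind": "two_block_hinge", "hinge_angle": 30, "noise": 0.2, "seed": 1048, "sequence": "MVVTHHQICNAEWCTDAIWKNVIYTWFYWVITFVLCEEAWIFMACTKFSLFDCVQKIRMCVMFETFHSVHIMKHHWNIMRYSNHQ", "name": "outward_4"}}}
  ],
  "naive": {"k": 2}
}
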