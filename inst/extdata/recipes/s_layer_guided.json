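{
  "comment": "Guided homodimer recipe: a self-assembly-like dimer steered by a polyalanine two-chain interface template over the mock backend. The MSA is masked across the loop window so the templated contact is not out-competed.",
  "mode": "guided",
  "seed": 1,
  "n_models": 1,
  "backend": "mock",
  "chains": [
    {"chain_id": "M", "sequence": "LNMNIDEVMQWSIRHFMNYCWRRTFNTQMV", "copies": 2}
  ],
  "msa": [
    {
      "source": {"toy": {"n_rows": 20, "conservation": 0.85, "seed": 11}},
      "mask": [{"chain": "M", "start": 8, "end": 26}]
    }
  ],
  "templates": [
    {
      "name": "interface_dimer",
      "source": {"fixture": {"kind": "toy_complex", "length": 30, "seed": 5,
                              "sequence": "LNMNIDEVMQWSIRHFMNYCWRRTFNTQMV"}},
      "assignments": [
        {"chain": "A", "start": 1, "end": 30, "source_chain": "A"},
        {"chain": "B", "start": 1, "end": 30, "source_chain": "B"}
      ],
      "relabel": {"mode": "polyalanine"},
      "truncate_cbeta": true
    }
  ],
  "declared_interfaces": [["A", "B"]]
}
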