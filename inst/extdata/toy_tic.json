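{
  "id": "toy_tic",
  "name": "Two-metabolite toy network with a thermodynamically infeasible cycle",
  "metabolites": [
    {"id": "A", "name": "metabolite A", "compartment": "c"},
    {"id": "B", "name": "metabolite B", "compartment": "c"}
  ],
  "reactions": [
    {
      "id": "v1",
      "name": "uptake of A",
      "metabolites": {"A": 1.0},
      "lower_bound": 0.0,
      "upper_bound": 1000.0,
      "gene_reaction_rule": "g1",
      "subsystem": "Exchange"
    },
    {
      "id": "v2",
      "name": "A to B",
      "metabolites": {"A": -1.0, "B": 1.0},
      "lower_bound": 0.0,
      "upper_bound": 1000.0,
      "gene_reaction_rule": "g2",
      "subsystem": "Cycle"
    },
    {
      "id": "v3",
      "name": "B to A",
      "metabolites": {"A": 1.0, "B": -1.0},
      "lower_bound": 0.0,
      "upper_bound": 1000.0,
      "gene_reaction_rule": "g3",
      "subsystem": "Cycle"
    },
    {
      "id": "v4",
      "name": "secretion of B",
      "metabolites": {"B": -1.0},
      "lower_bound": 0.0,
      "upper_bound": 1000.0,
      "gene_reaction_rule": "g4",
      "subsystem": "Exchange"
    }
  ],
  "genes": [
    {"id": "g1", "name": "g1"},
    {"id": "g2", "name": "g2"},
    {"id": "g3", "name": "g3"},
    {"id": "g4", "name": "g4"}
  ],
  "compartments": {"c": "cytosol"},
  "version": "1"
}
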