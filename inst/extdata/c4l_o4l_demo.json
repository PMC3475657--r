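{
  "name": "c4l_o4l_demo",
  "n_steps": 4,
  "transitions": [
    {
      "edge": "C0C1",
      "k_forward": 2,
      "k_backward": 10,
      "ligand_dependent": true
    },
    {
      "edge": "C1C2",
      "k_forward": 4,
      "k_backward": 2,
      "ligand_dependent": true
    },
    {
      "edge": "C2C3",
      "k_forward": 2,
      "k_backward": 2,
      "ligand_dependent": true
    },
    {
      "edge": "C3C4",
      "k_forward": 20,
      "k_backward": 100,
      "ligand_dependent": true
    },
    {
      "edge": "O0O1",
      "k_forward": 2,
      "k_backward": 0.33333333333333331,
      "ligand_dependent": true
    },
    {
      "edge": "O1O2",
      "k_forward": 4,
      "k_backward": 0.16666666666666666,
      "ligand_dependent": true
    },
    {
      "edge": "O2O3",
      "k_forward": 10,
      "k_backward": 9,
      "ligand_dependent": true
    },
    {
      "edge": "O3O4",
      "k_forward": 4,
      "k_backward": 20,
      "ligand_dependent": true
    },
    {
      "edge": "C0O0",
      "k_forward": 0.5,
      "k_backward": 3,
      "ligand_dependent": false
    },
    {
      "edge": "C1O1",
      "k_forward": 10,
      "k_backward": 2,
      "ligand_dependent": false
    },
    {
      "edge": "C2O2",
      "k_forward": 1.2,
      "k_backward": 0.02,
      "ligand_dependent": false
    },
    {
      "edge": "C3O3",
      "k_forward": 200,
      "k_backward": 3,
      "ligand_dependent": false
    },
    {
      "edge": "C4O4",
      "k_forward": 200,
      "k_backward": 3,
      "ligand_dependent": false
    }
  ]
}
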