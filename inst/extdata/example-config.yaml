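# Example run configuration. Every value shown is the shipped default;
# omit any field to inherit it.
seed: 1
systems:
  - id: WT
    structure: wt.pdb            # PDB path
    topology: wt_topology.json   # optional explicit spring table
    phenotypes: [trophic, nociceptive]
  - id: VAR
    structure: var.pdb
    topology: var_topology.json
    phenotypes: [trophic]
nma:
  cutoff: 10          # ENM contact cutoff, Angstrom
  springConstant: 1
  nModes: 20          # lowest non-trivial modes analysed
  amplitude: 1.0      # MRMS displacement, Angstrom
  nFrames: 21         # odd, so the reference frame is included
  relax: true
  restraintWeight: 50
similarity:
  rThreshold: 0.6     # |r| edge threshold
  pThreshold: 0.001
  nPermutations: 9999
network:
  corrThreshold: 0.7  # |C| edge threshold
  distThreshold: 10   # contact distance, Angstrom
  frameFraction: 0.75 # fraction of frames the contact must hold
  modularityTolerance: 0.05
  minCommunitySize: 10
  kPaths: 500
paths:
  endpoints: ~        # list of [source, sink] residue keys; ~ = automatic
interactions:
  hbondDist: 3.0      # donor-acceptor distance, Angstrom
  hbondAngle: 20      # deviation from linearity, degrees
  saltBridgeDist: 3.2 # oxygen-nitrogen distance, Angstrom
  occupancy: 0.5      # high-occupancy screen (inclusive)
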