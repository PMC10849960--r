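Optional local inputs (not distributed):

  8GJG.pdb, 8GJI.pdb - crystal structures of the two glucagon binders.
  Download from the PDB and place here to enable the crystal-structure
  shape-complementarity and contact-molecular-surface checks in
  tests/testthat/test-acceptance.R.
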