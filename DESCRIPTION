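Package: HelixGroove
Title: Parametric Groove Scaffolds and Sequence-Space Annealing for Helical Peptide Binder Design
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing proteins that cradle alpha-helical peptides in an
    open groove. Generates helical-bundle backbones from the Crick coiled-coil
    parameterization, randomly samples five-helix groove scaffolds around a
    central target-helix slot, closes the helices into a single chain with
    geometric loops, threads target peptide sequences onto a bound helix with
    hydrophobic-interface filtering, computes interface and compactness metrics
    (radius of gyration and its guiding potential, distogram contact
    probability, interface predicted aligned error, Lawrence-Colman shape
    complementarity, contact molecular surface, Shrake-Rupley solvent
    accessibility), and runs Metropolis simulated annealing in sequence space
    against a pluggable structure-prediction oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: StructuralPrediction, Proteomics, Software
RoxygenNote: 7.3.3
Collate: 
    'utils-geometry.R'
    'AllGenerics.R'
    'AllClasses.R'
    'HelixGroove-package.R'
    'axis.R'
    'config.R'
    'crick.R'
    'filters.R'
    'fixtures.R'
    'hallucinate.R'
    'io-pdb.R'
    'loops.R'
    'metrics-distogram.R'
    'metrics-rg.R'
    'metrics-surface.R'
    'oracle-toy.R'
    'sampler.R'
    'threading.R'
    'utils-aa.R'
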