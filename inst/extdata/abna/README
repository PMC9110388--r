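Deposited crystal structures are not redistributed with the package.
To run the crystal-geometry checks, place the PDB-format files

    5HO2.pdb  5HO0.pdb  5HP6.pdb

(downloadable from the wwPDB) in this directory before installation, or
point the tests at an external copy with

    options(pincerflex.pdb_dir = "/path/to/pdb/files")
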