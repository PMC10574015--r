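# Crystal reference structures

The crystal-reference comparisons (active 5XRA, agonist-bound 5XR8,
antagonist-bound 5TGZ) require the original PDB entries, which are not
redistributable with this package.  To enable those checks, download

    https://files.rcsb.org/download/5XRA.pdb
    https://files.rcsb.org/download/5XR8.pdb
    https://files.rcsb.org/download/5TGZ.pdb

into this directory as `5xra.pdb`, `5xr8.pdb`, `5tgz.pdb` before
installing the package.
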