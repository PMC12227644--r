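file	md5
fusions.tsv	75ffd64dec751256e396aa2c21463009
subjects.tsv	339280197ffc9424990662f8bbbc1e63
partners.tsv	6b04036cdd060bfab47cace6bce68671
gene_locations.tsv	b2e52ea4a9e55c78ed39b532e124c758
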