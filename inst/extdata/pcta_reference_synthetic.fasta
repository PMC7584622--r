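>PctA_synthetic synthetic PctA surrogate; dCache_1 domain 36-261; pocket Y101 M111 Y121 R126 W128 Y144 D146 A147 D173
DPVVVHLWGAWSYGQVHVCCMVNNPHYSFWGKGWAWKIWFLQIGWGNSNFRERQDMQMCN
LKPVGCQEEVKWMCEKFKHWNFCFTILHSMDDAWLKRMFIYNEKSIYQPLMTFGYQETWL
YDYFIRHWMFMADMFMAKCWCNCYLDACYQMVTHYTGAKGEFRMWAAYPTCLDWAQKHHD
QYLVQQGFYATYCQWGCGLLMYWTRWSAHCMDGFPVKCESLPVCAIPMNPNFEDDSHYPG
YCAFKEIWVQVFWVRLMTFWHEYAHDPRTMNNHRRNRMGYYILLHNEWALMAIMPAVIKR
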