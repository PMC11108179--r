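# Electron-tower midpoint potentials (V vs SHE, pH 7) shipped as an example
# override file for read_potential_table(); same values as the built-in table.
name,E0_prime,n_electrons,n_protons,oxidized_label,reduced_label
PCA,-0.240,2,2,PCA_ox,PCA_red
pyocyanin,-0.040,2,2,PYO_ox,PYO_red
menaquinone,-0.074,2,2,MQ,MQH2
demethylmenaquinone,0.036,2,2,DMQ,DMQH2
ubiquinone,0.100,2,2,UQ,UQH2
fumarate,0.033,2,0,fumarate,succinate
TMAO,0.130,2,2,TMAO,TMA
DMSO,0.160,2,2,DMSO,DMS
nitrate,0.433,2,2,NO3-,NO2-
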