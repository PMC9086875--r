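item_id,unit_cost_eur,price_year,source
the_box,318,2020,Bills
stress_echo,542,2020,LUMC
tte,117,2020,LUMC
holter,152,2020,LUMC
e_visit,44,2020,LUMC
in_office,96,2020,LUMC
technical_support,1758,2020,Bills
np_contact,4,2020,Dutch costing guidelines
catheterization,2037,2020,NZA
pci_1v,5999,2020,NZA
pci_mv,6428,2020,NZA
admission_night,684,2020,Dutch costing guidelines
inhospital_support,15367,2020,UMC gross salary of 0.5 FTE
emergency_visit,276,2020,Dutch costing guidelines (price not itemised in bills)
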