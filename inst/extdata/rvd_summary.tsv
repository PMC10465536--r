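# rumenvirome-ruleset/1.0: metric	numerator	denominator	printed_percent	digits
genus_assigned_votus	1857	397180	0.47	2
family_assigned_votus	32934	397180	8.3	1
crass_like_votus	121	397180	0.03	2
bacteriophages_multi_species	9214	40881	22.5	1
archaeophages_multi_species	396	2403	16.5	1
cross_phylum_phages	1544	40881	3.8	1
host_matched_archaeophages	2403	NA	NA	NA
host_matched_bacteriophages	40881	NA	NA	NA
host_matched_total	43284	NA	NA	NA
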