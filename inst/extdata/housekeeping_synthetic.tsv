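gene_id	namespace	label
hkChs01	housekeeping	chitin_synthase
hkChs02	housekeeping	chitin_synthase
hkChs03	housekeeping	chitin_synthase
hkChs04	housekeeping	chitin_synthase
hkChs05	housekeeping	chitin_synthase
hkChs06	housekeeping	chitin_synthase
hkChs07	housekeeping	chitin_synthase
hkChs08	housekeeping	chitin_synthase
hkChs09	housekeeping	chitin_synthase
hkChs10	housekeeping	chitin_synthase
hkChs11	housekeeping	chitin_synthase
hkNdh01	housekeeping	NADH_dehydrogenase
hkNdh02	housekeeping	NADH_dehydrogenase
hkNdh03	housekeeping	NADH_dehydrogenase
hkNdh04	housekeeping	NADH_dehydrogenase
hkNdh05	housekeeping	NADH_dehydrogenase
hkNdh06	housekeeping	NADH_dehydrogenase
hkNdh07	housekeeping	NADH_dehydrogenase
hkNdh08	housekeeping	NADH_dehydrogenase
hkNdh09	housekeeping	NADH_dehydrogenase
hkNdh10	housekeeping	NADH_dehydrogenase
hkNdh11	housekeeping	NADH_dehydrogenase
hkNdh12	housekeeping	NADH_dehydrogenase
hkNdh13	housekeeping	NADH_dehydrogenase
hkNdh14	housekeeping	NADH_dehydrogenase
hkNdh15	housekeeping	NADH_dehydrogenase
hkNdh16	housekeeping	NADH_dehydrogenase
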