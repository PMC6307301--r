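genome_id	group
genome01	PlantedFam01
genome02	PlantedFam01
genome03	PlantedFam01
genome04	PlantedFam03
genome05	PlantedFam03
genome06	PlantedFam03
genome07	PlantedFam05
genome08	PlantedFam05
genome09	PlantedFam05
genome10	PlantedFam05
genome11	PlantedFam02
genome12	PlantedFam02
genome13	PlantedFam02
genome14	PlantedFam04
genome15	PlantedFam04
genome16	PlantedFam04
genome17	Family01
genome18	Family01
genome19	Family01
genome20	Family01
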