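area_description,occupancy_factor
"Offices, labs, pharmacies, receptionist areas, attended waiting rooms, kids' play areas, imaging rooms, film reading areas, nursing stations, control rooms",1
"Patient exam rooms, patient treatment rooms, nuclear medicine hot labs, PET uptake rooms",0.5
"Corridors, patient rooms, employee lounges, staff rest rooms",0.2
"Corridor doors",0.125
"Public toilets, vending areas, storage rooms, outdoor areas with seating, unattended waiting rooms, patient holding",0.05
"Outdoors, unattended parking lots, attics, stairways, unattended elevators, janitor's closets",0.025
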