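parent_id,metabolite_id,reaction_class,site_relation,dominant_other_site,conjugated_to_olefin,expected_direction
AMPH,4-OH-AMPH,aromatic_hydroxylation,creates_new_reactive_group,FALSE,FALSE,faster
DIC,5-OH-DIC,aromatic_hydroxylation,creates_new_reactive_group,FALSE,FALSE,faster
NEV,2-OH-NEV,aromatic_hydroxylation,creates_new_reactive_group,FALSE,FALSE,faster
DRT,3-OH-DRT,aromatic_hydroxylation,creates_new_reactive_group,FALSE,FALSE,faster
ATV,p-OH-ATV,aromatic_hydroxylation,creates_new_reactive_group,TRUE,FALSE,similar
EFV,8-OH-EFV,aromatic_hydroxylation,creates_new_reactive_group,FALSE,FALSE,faster
IBU,1-OH-IBU,alkyl_hydroxylation,remote_from_most_reactive_site,FALSE,FALSE,similar
TSM,OH-TSM,alkyl_hydroxylation,remote_from_most_reactive_site,FALSE,FALSE,similar
NEV,12-OH-NEV,alkyl_hydroxylation,remote_from_most_reactive_site,FALSE,FALSE,similar
CLR,CLR-N-ox,n_oxidation,at_most_reactive_site,FALSE,FALSE,slower
PHEN,PHEN-N-ox,n_oxidation,at_most_reactive_site,FALSE,FALSE,slower
LID,LID-N-ox,n_oxidation,at_most_reactive_site,FALSE,FALSE,slower
TMN,TMN-N-ox,n_oxidation,remote_from_most_reactive_site,FALSE,FALSE,similar
MIA,MIA-N-ox,n_oxidation,remote_from_most_reactive_site,FALSE,FALSE,similar
RNT,RNT-N-ox,n_oxidation,remote_from_most_reactive_site,FALSE,FALSE,similar
OSE,OSE-acid,carboxylic_acid_formation,remote_from_most_reactive_site,FALSE,TRUE,faster
SMX,N4-acetyl-SMX,acetylation,at_most_reactive_site,FALSE,FALSE,slower
Desac-BIS,BIS,acetylation,at_most_reactive_site,FALSE,FALSE,slower
STZ,N4-acetyl-STZ,acetylation,remote_from_most_reactive_site,FALSE,FALSE,similar
Desac-DILT,DILT,acetylation,remote_from_most_reactive_site,FALSE,FALSE,similar
PCM,PCM-sulfate,sulfation,at_most_reactive_site,FALSE,FALSE,slower
DPH,DPH-N-gluc,glucuronidation,at_most_reactive_site,FALSE,FALSE,slower
SMX,SMX-N1-gluc,glucuronidation,at_most_reactive_site,FALSE,FALSE,slower
TMS,TMS-gluc,glucuronidation,remote_from_most_reactive_site,FALSE,FALSE,similar
SRT,N-DesMe-SRT,n_dealkylation,at_most_reactive_site,FALSE,FALSE,slower
VEN,O-DesMe-VEN,o_dealkylation,creates_new_reactive_group,FALSE,FALSE,faster
DXM,DXT,o_dealkylation,creates_new_reactive_group,FALSE,FALSE,faster
MPA,6-O-DesMe-MPA,o_dealkylation,creates_new_reactive_group,TRUE,FALSE,similar
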