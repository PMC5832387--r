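side_effect	organ	sub_system	system
nausea	stomach	gastrointestinal	digestive
vomiting	stomach	gastrointestinal	digestive
dyspepsia	stomach	gastrointestinal	digestive
gastric ulcer	stomach	gastrointestinal	digestive
diarrhoea	intestine	gastrointestinal	digestive
constipation	intestine	gastrointestinal	digestive
abdominal pain	intestine	gastrointestinal	digestive
ileus	intestine	gastrointestinal	digestive
hepatitis	liver	hepatobiliary	digestive
jaundice	liver	hepatobiliary	digestive
hepatic failure	liver	hepatobiliary	digestive
cholelithiasis	gallbladder	hepatobiliary	digestive
rash	skin	integument	integumentary
pruritus	skin	integument	integumentary
urticaria	skin	integument	integumentary
alopecia	hair	integument	integumentary
onycholysis	nails	integument	integumentary
headache	brain	central_nervous	nervous
dizziness	brain	central_nervous	nervous
seizure	brain	central_nervous	nervous
somnolence	brain	central_nervous	nervous
tremor	brain	central_nervous	nervous
neuropathy peripheral	peripheral_nerves	peripheral_nervous	nervous
paraesthesia	peripheral_nerves	peripheral_nervous	nervous
hypoaesthesia	peripheral_nerves	peripheral_nervous	nervous
palpitations	heart	cardiac	cardiovascular
tachycardia	heart	cardiac	cardiovascular
bradycardia	heart	cardiac	cardiovascular
myocardial infarction	heart	cardiac	cardiovascular
hypertension	blood_vessels	vascular	cardiovascular
hypotension	blood_vessels	vascular	cardiovascular
vasculitis	blood_vessels	vascular	cardiovascular
anaemia	blood	haematic	cardiovascular
thrombocytopenia	blood	haematic	cardiovascular
neutropenia	blood	haematic	cardiovascular
neurotoxicity	misc_nervous	central_nervous	nervous
encephalopathy syndrome	misc_nervous	central_nervous	nervous
pain	MISC	MISC	MISC
discomfort	MISC	MISC	MISC
fatigue	MISC	MISC	MISC
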