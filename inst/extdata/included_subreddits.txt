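# Health-relevant subreddits for the final restriction step: the forums in
# which post-topic analysis is run. Seeded from the subreddits tabulated in
# the published per-subreddit post-count analysis; user-replaceable.
askreddit
askdocs
amitheasshole
relationship_advice
relationships
medical
skincareaddiction
legaladvice
advice
teenagers
adhd
babybumps
testosterone
std
anxiety
depression
pregnant
birthcontrol
childfree
hypothyroidism
fitness
mentalhealth
diabetes
dentistry
science
diagnoseme
infertility
suicidewatch
optometry
ibs
crohnsdisease
cancer
fibromyalgia
chronicpain
multiplesclerosis
aspergers
bpd
sleepapnea
bipolarreddit
cfs
askdoctorsmeeee
askdoctors
rheumatoid
medicine
eczema
asthma
interstitialcystitis
nutrition
dementia
askscience
healthcare
stopsmoking
dysautonomia
psoriasis
keratoconus
pharmacy
vegetarian
massage
kidneystones
gravesdisease
menieres
pilonidalcyst
posture
paleo
gastroparesis
hemophilia
psychology
troubledteens
pancreaticcancer
amblyopia
lactoseintolerant
alternativehealth
naturalbeauty
publichealth
transplant
caregiversupport
hepc
chd
flu
juicing
pescetarian
ukhealthcare
dystonia
itsneverlupus
maculardegeneration
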