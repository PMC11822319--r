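# Default health-topic keyword lexicon: 81 named topics in 16 medical
# disciplines; the reserved fallback topic "nonmedical" (its own 17th
# discipline) is implicit and added by the loader, for 82 topics in 17
# disciplines overall.
#
# Disciplines are chapter-level groupings modeled on the ICD-10; "medical;
# other" collects health-system topics (e.g. medical billing) with no ICD-10
# counterpart. Keyword lists are a reconstruction seeded from phrases quoted
# in the published taxonomy (e.g. "antibiotics", "gonorrhea", "chlamydia",
# "bacterial vaginosis" for STIs; "difficulty urinating" / "difficulty
# peeing" for benign prostatic hypertrophy) and are deliberately kept
# pairwise disjoint after lemmatization; extend them for serious use.
# Topic order within the file is the assignment tie-break of last resort.
disciplines:
  psychiatry and mental health:
    anxiety: [anxiety, panic attack, anxious]
    addiction and drug use: [addiction, heroin, cocaine, drug test, overdose, opioid]
    ADHD: [adhd, adderall, attention deficit]
    obsessive-compulsive disorder: [ocd, obsessive compulsive, intrusive thoughts, compulsion]
    abuse: [abuse, abusive, gaslighting]
    PTSD: [ptsd, flashbacks, traumatic]
    depression: [depression, depressed, antidepressant]
    alcoholism: [alcoholic, alcoholism, hangover]
    autism: [autism, autistic, asperger]
    psychiatry: [psychiatrist, psych ward, bipolar]
    tobacco use: [smoking, nicotine, cigarette, vaping]
    LGBTQ health: [lgbt, transgender, hormone therapy]
    body dysmorphic disorder: [body dysmorphia, dysmorphic]
    dementia: [dementia, alzheimer, memory loss]
  genitourinary and reproductive health:
    pregnancy: [pregnant, pregnancy, prenatal, trimester]
    menstrual cycle: [menstrual, ovulation, tampon, late period]
    male reproductive health: [erectile, sperm, vasectomy, foreskin]
    testosterone use: [testosterone, low t, androgel]
    urinary tract infection: [uti, urinary tract, cystitis]
    HPV: [hpv, papillomavirus, genital warts, pap smear]
    miscarriage: [miscarriage, stillbirth]
    female reproductive health: [ovarian cyst, vaginal discharge, labia]
    endometriosis: [endometriosis, endometrial]
    benign prostatic hypertrophy: [prostate, difficulty urinating, difficulty peeing]
    nephrology; unspecified: [kidney, dialysis, creatinine]
    gestational diabetes: [gestational, glucose tolerance]
    testicular torsion: [testicular torsion, twisted testicle]
  infectious diseases:
    STIs: [chlamydia, gonorrhea, syphilis, herpes, bacterial vaginosis, antibiotics, std]
    HIV: [hiv, antiretroviral, seroconversion]
    influenza: [influenza, flu shot, flu]
    measles: [measles, mmr]
    infectious mononucleosis: [mononucleosis, epstein barr]
    Lyme disease: [lyme, tick bite]
    vaccination: [vaccine, vaccination, immunization, booster]
  endocrinology, nutrition, and metabolism:
    hypothyroidism: [hypothyroid, hypothyroidism, levothyroxine, hashimoto]
    vitamins: [vitamin, supplement, multivitamin]
    diabetes: [diabetes, diabetic, insulin, a1c]
    dieting: [diet, keto, calorie, fasting]
    PCOS: [pcos, polycystic]
    bodybuilding: [bodybuilding, protein powder, creatine]
    obesity: [obesity, obese, weight loss]
    hyperthyroidism: [hyperthyroid, hyperthyroidism, graves disease]
    endocrinology: [endocrinologist, hormone levels, cortisol]
    thyroid; unspecified: [thyroid, tsh]
  hematology and immunology:
    allergies: [allergy, allergic, antihistamine, hives]
    anemia: [anemia, anemic, iron deficiency]
    hematology: [hematologist, blood count, platelet, clotting]
    autoimmune disease: [autoimmune, lupus, rheumatoid]
  ophthalmology:
    eye disorder: [glasses, cataract, glaucoma, eye exam, blurry]
    vision correction: [lasik, contact lenses, laser eye]
  musculoskeletal and connective tissue conditions:
    musculoskeletal conditions: [muscle, sprain, tendon, ligament]
    back pain: [back pain, sciatica, slipped disc]
    arthritis: [arthritis, joint pain]
    fibromyalgia: [fibromyalgia, fibro, chronic fatigue]
  gastroenterology:
    gallbladder disorder: [gallbladder, gallstone]
    irritable bowel syndrome: [ibs, irritable bowel, bloating]
    celiac disease: [celiac, gluten]
    acid reflux: [acid reflux, heartburn, gerd]
  dermatology:
    dermatology; unspecified: [rash, mole, itchy, dermatologist]
    eczema: [eczema, dry skin]
    acne: [acne, pimple, accutane]
    psoriasis: [psoriasis, scaly skin]
  neurology:
    migraine: [migraine, headache, aura]
    epilepsy: [epilepsy, seizure]
    multiple sclerosis: [multiple sclerosis, demyelinating, numbness]
    sleep disorders: [insomnia, sleep apnea, narcolepsy, melatonin]
  cardiovascular:
    arrhythmia: [arrhythmia, palpitations, afib, heart rate]
    hypertension: [blood pressure, hypertension]
    heart disease: [heart attack, cholesterol, chest pain, cardiologist]
  pulmonology:
    asthma: [asthma, inhaler, wheezing]
    respiratory infection: [bronchitis, pneumonia, sore throat, cough]
    cystic fibrosis: [cystic fibrosis, sweat test]
  medical; other:
    medical billing: [billing, insurance claim, copay, deductible]
    dating: [dating, boyfriend, girlfriend, tinder]
  neoplasms:
    testicular cancer: [testicular cancer, testicle lump]
    breast cancer: [breast cancer, mammogram, breast lump]
    skin cancer: [melanoma, skin cancer, basal cell]
  dentistry:
    dentistry: [dentist, cavity, root canal, wisdom tooth]
    orthodontics: [braces, orthodontist, invisalign]
  otolaryngology:
    hearing loss: [hearing loss, hearing aid, deaf]
    tinnitus: [tinnitus, ringing ears, earwax]
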