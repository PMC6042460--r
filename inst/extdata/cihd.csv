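code,component,description,chapter
s410,body_structure,Structure of cardiovascular system,"Structures of the cardiovascular, immunological and respiratory systems"
s430,body_structure,Structure of respiratory system,"Structures of the cardiovascular, immunological and respiratory systems"
b130,body_function,Energy and drive functions,Mental functions
b134,body_function,Sleep functions,Mental functions
b144,body_function,Memory functions,Mental functions
b152,body_function,Emotional functions,Mental functions
b410,body_function,Heart functions,"Functions of the cardiovascular, hematological, immunological and respiratory systems"
b415,body_function,Blood vessel functions,"Functions of the cardiovascular, hematological, immunological and respiratory systems"
b420,body_function,Blood pressure functions,"Functions of the cardiovascular, hematological, immunological and respiratory systems"
b455,body_function,Exercise tolerance functions,"Functions of the cardiovascular, hematological, immunological and respiratory systems"
b460,body_function,Sensations associated with cardiovascular and respiratory functions,"Functions of the cardiovascular, hematological, immunological and respiratory systems"
b530,body_function,Weight maintenance functions,"Functions of the digestive, metabolic and endocrine systems"
b730,body_function,Muscle power functions,Neuromusculoskeletal and movement-related functions
b740,body_function,Muscle endurance functions,Neuromusculoskeletal and movement-related functions
d230,activity_participation,Carrying out daily routine,General tasks and demands
d240,activity_participation,Handling stress and other psychological demands,General tasks and demands
d430,activity_participation,Lifting and carrying objects,Mobility
d450,activity_participation,Walking,Mobility
d455,activity_participation,Moving around,Mobility
d460,activity_participation,Moving around in different locations,Mobility
d570,activity_participation,Looking after one's health,Self-care
d620,activity_participation,Acquisition of goods and services,Domestic life
d630,activity_participation,Preparing meals,Domestic life
d640,activity_participation,Doing housework,Domestic life
d760,activity_participation,Family relationships,Interpersonal interactions and relationships
d770,activity_participation,Intimate relationships,Interpersonal interactions and relationships
d850,activity_participation,Remunerative employment,Major life areas
d870,activity_participation,Economic self-sufficiency,Major life areas
d920,activity_participation,Recreation and leisure,"Community, social and civic life"
e110,environment,Products or substances for personal consumption,Products and technology
e125,environment,Products and technology for communication,Products and technology
e155,environment,"Design, construction and building products and technology of buildings for private use",Products and technology
e225,environment,Climate,Natural environment and human-made changes to environment
e250,environment,Sound,Natural environment and human-made changes to environment
e260,environment,Air quality,Natural environment and human-made changes to environment
e310,environment,Immediate family,Support and relationships
e315,environment,Extended family,Support and relationships
e320,environment,Friends,Support and relationships
e325,environment,"Acquaintances, peers, colleagues, neighbors, and community members",Support and relationships
e330,environment,People in positions of authority,Support and relationships
e355,environment,Health professionals,Support and relationships
e410,environment,Individual attitudes of immediate family members,Attitudes
e450,environment,Individual attitudes of health professionals,Attitudes
e570,environment,"Social security services, systems and policies","Services, systems and policies"
e575,environment,"General social support services, systems and policies","Services, systems and policies"
e580,environment,"Health services, systems and policies","Services, systems and policies"
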