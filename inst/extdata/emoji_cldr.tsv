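# Pinned subset of Unicode CLDR emoji short names (CLDR v44 annotation style).
# codepoint(hex)<TAB>short name
1F525	fire
2764	red heart
1F49A	green heart
1F499	blue heart
1F5A4	black heart
1F90D	white heart
1F600	grinning face
1F601	beaming face with smiling eyes
1F602	face with tears of joy
1F923	rolling on the floor laughing
1F60A	smiling face with smiling eyes
1F60D	smiling face with heart-eyes
1F970	smiling face with hearts
1F618	face blowing a kiss
1F60E	smiling face with sunglasses
1F929	star-struck
1F914	thinking face
1F633	flushed face
1F62D	loudly crying face
1F621	pouting face
1F92F	exploding head
1F973	partying face
1F637	face with medical mask
1F634	sleeping face
1F924	drooling face
1F61C	winking face with tongue
1F389	party popper
1F38A	confetti ball
1F4A8	dashing away
1F4A5	collision
1F4A6	sweat droplets
1F4AF	hundred points
1F44D	thumbs up
1F44C	OK hand
1F91D	handshake
1F64C	raising hands
1F64F	folded hands
1F4AA	flexed biceps
1F918	sign of the horns
1F919	call me hand
270C	victory hand
1F680	rocket
2B50	star
2728	sparkles
1F31F	glowing star
26A1	high voltage
1F308	rainbow
1F32A	tornado
1F32C	wind face
1F343	leaf fluttering in wind
1F331	seedling
1F353	strawberry
1F349	watermelon
1F34A	tangerine
1F34B	lemon
1F347	grapes
1F351	peach
1F34E	red apple
1F96D	mango
1F965	coconut
1F352	cherries
1F366	soft ice cream
1F36C	candy
1F36D	lollipop
1F370	shortcake
2615	hot beverage
1F6D2	shopping cart
1F6CD	shopping bags
1F4E6	package
1F4F8	camera with flash
1F6A8	police car light
26A0	warning
1F195	NEW button
1F6AC	cigarette
1F911	money-mouth face
1F4B0	money bag
1F4B8	money with wings
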