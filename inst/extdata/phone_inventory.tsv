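symbol	category	classes	classes_when_long	notes
p	consonant			bilabial plosive
b	consonant			bilabial plosive, voiced
t	consonant			dental plosive
d	consonant			dental plosive, voiced
ʈ	consonant			retroflex plosive
ɖ	consonant			retroflex plosive, voiced
k	consonant	velar		velar plosive
g	consonant	velar		velar plosive, voiced
m	consonant			bilabial nasal
n	consonant			dental nasal
ɳ	consonant			retroflex nasal
ŋ	consonant	velar		velar nasal
r	consonant	trill		alveolar trill
ʀ	consonant	trill		uvular trill; source table prints two identical trill cells, read as alveolar + uvular
ɾ	consonant			alveolar tap
f	consonant	fricative		labiodental fricative
v	consonant	fricative,voiced-fricative		labiodental fricative, voiced
s	consonant	fricative		dental fricative
ʂ	consonant	fricative		retroflex fricative
ʐ	consonant	fricative,voiced-fricative		retroflex fricative, voiced
ɕ	consonant	fricative		alveolo-palatal fricative; listed with the fricative class though absent from the consonant chart
ʝ	consonant	fricative,voiced-fricative		palatal fricative, voiced
ɧ	consonant	velar,fricative		velar/dorsal fricative; member of both the velar and fricative classes
ʁ	consonant	fricative,voiced-fricative		uvular fricative, voiced
h	consonant	fricative		glottal fricative
ɹ	consonant	liquid		alveolar approximant
l	consonant	liquid		lateral approximant
ɭ	consonant	liquid		retroflex lateral approximant
j	consonant			palatal approximant
i	vowel			close front unrounded
y	vowel		long-front-rounded-vowel	close front rounded; complexity class requires the length mark
ʉ	vowel		long-front-rounded-vowel	close central-front rounded; third class member is a documented assumption, override via config
u	vowel			close back rounded
ɪ	vowel			near-close front unrounded
ʏ	vowel			near-close front rounded
ʊ	vowel			near-close back rounded
e	vowel			close-mid front unrounded
ø	vowel		long-front-rounded-vowel	close-mid front rounded; complexity class requires the length mark
ɵ	vowel			close-mid central rounded
o	vowel			close-mid back rounded
ə	vowel			mid central
ɛ	vowel			open-mid front unrounded
œ	vowel			open-mid front rounded
ɔ	vowel			open-mid back rounded
æ	vowel			near-open front unrounded
a	vowel			open front unrounded
ɑ	vowel			open back unrounded
C	unknown-consonant			unrecognizable consonant-like segment; counts for syllable structure, earns no class points
V	unknown-vowel			unrecognizable vowel-like segment; counts as a nucleus, earns no class points
□	indeterminate			segment of undeterminable type; contributes nothing to scoring
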