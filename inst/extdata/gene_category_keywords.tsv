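keyword	category
auxin	hormone
abscisic	hormone
cytokinin	hormone
ethylene	hormone
gibberellin	hormone
brassinosteroid	hormone
IAA	hormone
cellulose	cell wall
expansin	cell wall
xyloglucan	cell wall
lignin	cell wall
phenylpropanoid	cell wall
phenylalanine ammonia-lyase	cell wall
pectin	cell wall
sucrose	sugar
glucose	sugar
amylase	sugar
trehalose	sugar
sugar transporter	sugar
photosystem	photosynthesis
chlorophyll	photosynthesis
cryptochrome	photosynthesis
phytochrome	photosynthesis
far-red	photosynthesis
actin	cytoskeleton
tubulin	cytoskeleton
kinesin	cytoskeleton
myosin	cytoskeleton
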