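word	ipa
bat	bæt
pat	pæt
cat	kæt
mat	mæt
bought	bɔːt
moon	muːn
thermometer	θəmɒmɪtə
change	tʃeɪndʒ
love	lʌv
remove	rɪmuːv
officer	ɒfɪsə
mouthwash	maʊθwɒʃ
needle	niːdəl
oxygen	ɒksɪdʒən
mug	mʌɡ
leek	liːk
gorilla	ɡərɪlə
girl	ɡɜːl
leather	lɛðə
hammer	hæmə
guitar	ɡɪtɑː
tree	triː
dog	dɒɡ
fish	fɪʃ
ship	ʃɪp
sheep	ʃiːp
chin	tʃɪn
gin	dʒɪn
thin	θɪn
this	ðɪs
sing	sɪŋ
ring	rɪŋ
wing	wɪŋ
yes	jɛs
wet	wɛt
vet	vɛt
bet	bɛt
pet	pɛt
met	mɛt
net	nɛt
set	sɛt
get	ɡɛt
jet	dʒɛt
let	lɛt
red	rɛd
bed	bɛd
head	hɛd
book	bʊk
foot	fʊt
food	fuːd
mood	muːd
blue	bluː
shoe	ʃuː
two	tuː
toe	təʊ
go	ɡəʊ
no	nəʊ
boat	bəʊt
coat	kəʊt
goat	ɡəʊt
note	nəʊt
nose	nəʊz
rose	rəʊz
house	haʊs
mouse	maʊs
mouth	maʊθ
south	saʊθ
cow	kaʊ
now	naʊ
boy	bɔɪ
toy	tɔɪ
voice	vɔɪs
noise	nɔɪz
five	faɪv
nine	naɪn
time	taɪm
line	laɪn
day	deɪ
play	pleɪ
rain	reɪn
name	neɪm
face	feɪs
place	pleɪs
make	meɪk
take	teɪk
cake	keɪk
lake	leɪk
paper	peɪpə
water	wɔːtə
father	fɑːðə
mother	mʌðə
brother	brʌðə
sister	sɪstə
baby	beɪbi
lady	leɪdi
happy	hæpi
city	sɪti
very	vɛri
fire	faɪə
flower	flaʊə
world	wɜːld
word	wɜːd
bird	bɜːd
work	wɜːk
walk	wɔːk
talk	tɔːk
tick	tɪk
bar	bɑː
car	kɑː
farm	fɑːm
arm	ɑːm
art	ɑːt
heart	hɑːt
ball	bɔːl
call	kɔːl
tall	tɔːl
wall	wɔːl
saw	sɔː
law	lɔː
door	dɔː
more	mɔː
four	fɔː
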