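# Irrelevant-term exclusion list: posts whose text contains any of these
# phrases (matched on raw tokens, not lemmas) are dropped before topic
# assignment. Reconstruction; user-replaceable.
video game
xbox
playstation
crypto
bitcoin
homework
exam results
job interview
background check
credit score
spell check
fact check
sound check
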