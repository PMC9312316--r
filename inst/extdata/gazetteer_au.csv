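pattern,code
sydney,syd
melbourne,mel
brisbane,bne
perth,per
adelaide,adl
hobart,hob
canberra,cbr
darwin,drw
new south wales,nsw
nsw,nsw
victoria,vic
vic,vic
queensland,qld
qld,qld
western australia,wa
wa,wa
south australia,sa
sa,sa
tasmania,tas
tas,tas
australian capital territory,act
act,act
northern territory,nt
nt,nt
australia,au
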