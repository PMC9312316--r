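good	1.9
great	3.1
happy	2.7
love	3.2
hope	1.9
safe	1.8
recover	1.6
support	1.7
thanks	1.9
relief	1.6
positive	2.3
calm	1.3
better	1.9
win	2.8
help	1.7
bad	-2.5
terrible	-2.1
sad	-2.1
fear	-2.2
death	-2.9
sick	-1.8
panic	-2.4
crisis	-2.3
lockdown	-1.2
angry	-2.3
worse	-2.8
lost	-1.3
scared	-2.2
hate	-2.7
fail	-2.3
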