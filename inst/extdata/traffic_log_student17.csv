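id,event,time,event_value
00017,start_item,835.0,
00017,ACER_EVENT,837.6,'01000000000000000000000
00017,click,837.6,hit_p2
00017,ACER_EVENT,839.8,'11000000000000000000000
00017,click,839.8,hit_p1
00017,ACER_EVENT,841.1,'11000000000010000000000
00017,ACER_EVENT,841.7,'11000000000010000100000
00017,ACER_EVENT,842.7,'11000000010010000100000
00017,ACER_EVENT,844.8,'11000000010010000101000
00017,ACER_EVENT,846.4,'11000000010000000101000
00017,ACER_EVENT,847.4,'01000000010000000101000
00017,ACER_EVENT,848.4,'01000000010000000001000
00017,ACER_EVENT,850.6,'01000000000000000001000
00017,ACER_EVENT,851.6,'01000000010000000001000
00017,ACER_EVENT,852.5,'01000000000000000001000
00017,ACER_EVENT,853.4,'01000000100000000001000
00017,ACER_EVENT,853.7,'01000000100000010001000
00017,end_item,855.0,
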