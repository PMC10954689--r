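gene,barcode,is_empty
gene090,000112,FALSE
gene044,000123,FALSE
gene117,000131,FALSE
gene110,000232,FALSE
gene013,000311,FALSE
gene089,001022,FALSE
gene063,001201,FALSE
gene007,001220,FALSE
gene094,001302,FALSE
Empty_8,001330,TRUE
gene080,002012,FALSE
gene046,002021,FALSE
gene029,002101,FALSE
gene010,002130,FALSE
gene047,002210,FALSE
gene068,002303,FALSE
gene041,002320,FALSE
gene036,003011,FALSE
gene093,003023,FALSE
Empty_4,003032,TRUE
gene074,003102,FALSE
gene070,003120,FALSE
gene079,003230,FALSE
gene042,003301,FALSE
gene023,003310,FALSE
gene019,010013,FALSE
gene104,010022,FALSE
gene016,010102,FALSE
gene039,010203,FALSE
gene035,010210,FALSE
gene113,010301,FALSE
gene027,010320,FALSE
gene006,011002,FALSE
gene030,011020,FALSE
gene045,011200,FALSE
gene115,012001,FALSE
gene066,012100,FALSE
gene116,013003,FALSE
Empty_5,013030,TRUE
gene008,013300,FALSE
gene112,020012,FALSE
gene102,020021,FALSE
gene121,020101,FALSE
Empty_3,020230,TRUE
gene095,020303,FALSE
gene092,020310,FALSE
gene086,021001,FALSE
gene118,021010,FALSE
gene085,022030,FALSE
gene050,023002,FALSE
gene119,023020,FALSE
gene002,030011,FALSE
Empty_7,030023,TRUE
gene025,030032,FALSE
gene014,030201,FALSE
gene012,030220,FALSE
gene060,030302,FALSE
gene048,031100,FALSE
gene015,032002,FALSE
gene106,032020,FALSE
gene061,032300,FALSE
gene083,033010,FALSE
gene024,033200,FALSE
gene009,100012,FALSE
gene099,100021,FALSE
gene032,100033,FALSE
Empty_1,100103,TRUE
gene022,100130,FALSE
gene073,100320,FALSE
gene084,101020,FALSE
gene111,101300,FALSE
gene109,102030,FALSE
gene062,103003,FALSE
gene049,103200,FALSE
gene059,110020,FALSE
gene053,110200,FALSE
gene017,120003,FALSE
gene011,120010,FALSE
gene071,120100,FALSE
gene056,122000,FALSE
gene018,130030,FALSE
gene028,130300,FALSE
gene075,133000,FALSE
gene096,200023,FALSE
gene051,200032,FALSE
gene057,200102,FALSE
gene058,200110,FALSE
gene082,200201,FALSE
gene037,200303,FALSE
gene031,201001,FALSE
gene038,201010,FALSE
gene072,201200,FALSE
gene077,202300,FALSE
gene021,203002,FALSE
gene108,203030,FALSE
gene004,210002,FALSE
gene098,210010,FALSE
gene100,210100,FALSE
gene052,220001,FALSE
gene064,220300,FALSE
gene054,230003,FALSE
gene055,230020,FALSE
gene034,230200,FALSE
Empty_2,232000,TRUE
Empty_6,300013,TRUE
gene001,300022,FALSE
gene040,300031,FALSE
gene107,300101,FALSE
gene033,300120,FALSE
gene069,300203,FALSE
gene076,300230,FALSE
gene065,300302,FALSE
gene103,301003,FALSE
gene088,301030,FALSE
gene067,302002,FALSE
gene114,302010,FALSE
gene105,302200,FALSE
gene081,303001,FALSE
gene120,303020,FALSE
gene026,310003,FALSE
gene020,310030,FALSE
gene078,310300,FALSE
gene005,320002,FALSE
gene043,320020,FALSE
gene091,320200,FALSE
gene087,323000,FALSE
gene097,330001,FALSE
gene003,330010,FALSE
gene101,331000,FALSE
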