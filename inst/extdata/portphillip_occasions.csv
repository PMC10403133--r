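season_year,months,stanley_burnham_p,otis_p
2012,Nov-Dec-Jan-Feb-Mar,0.28,0.02
2013,Nov-Dec-Jan-Feb-Mar,0.10,2.00
2014,Nov-Dec-Jan-Feb-Mar,0.10,2.00
2015,Nov-Dec-Jan-Feb-Mar,0.80,2.00
2016,Nov-Jan-Mar,0.04,2.00
2017,Nov-Dec-Jan-Mar,0.25,0.20
2018,Nov-Dec-Jan-Feb-Mar,0.25,0.20
2019,Nov-Dec-Jan-Feb-Mar,0.80,2.00
2020,Jan-Feb-Mar-Apr,0.77,2.00
2021,Nov-Dec-Jan-Feb-Mar,0.05,2.00
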