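season_year,date_start,date_end,images
2012,2012-10-09,2013-04-06,328
2013,2013-10-26,2014-04-17,694
2014,2014-10-05,2015-03-21,75
2015,2015-10-17,2016-04-04,29
2016,2016-10-14,2017-04-24,37
2017,2017-10-13,2018-03-15,58
2018,2018-11-11,2019-04-24,357
2019,2019-10-01,2020-03-22,80
2020,2021-01-02,2021-04-22,263
2021,2021-11-17,2022-04-28,4073
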