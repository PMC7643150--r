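"year","monsoon_length_days","monsoon_precip_mm"
1987,60,190.9
1988,78,43.9
1989,109,183.1
1990,71,155.4
1991,78,291.7
1992,78,97.5
1993,82,173.9
1994,69,124.9
1995,62,127.8
1996,86,153.2
1997,69,104.2
1998,76,169.8
1999,75,109.6
2000,54,223.9
2001,80,174.4
2002,82,243.2
2003,73,100.2
2004,72,132.8
2005,71,182.7
2006,68,197.5
2007,81,177.9
2008,71,148.6
2009,72,124.1
2010,66,124.9
2011,88,240.4
2012,78,100.8
2013,73,182.1
2014,56,152
2015,64,138.2
2016,51,207
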