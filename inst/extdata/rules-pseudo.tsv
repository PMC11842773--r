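# Default pseudo-phase substitution rules.
# Applied, in order, to the trimmed lowercased raw string padded with one
# space on each side, so patterns may use spaces as word-boundary anchors.
# After the rule pass all whitespace and non-[a-z0-9] characters are deleted.
# Tab-separated: order, pattern, replacement.
order	pattern	replacement
10	**	
20	^	
30	.	 
40	,	 
50	(	 
60	)	 
70	[	 
80	]	 
90	/	 per 
100	%	 percent 
110	cm-2	 per centimetersquared 
120	km-2	 per kilometersquared 
130	mm-2	 per millimetersquared 
140	m-2	 per metersquared 
150	m-3	 per metercubed 
160	m-1	 per meter 
170	s-1	 per second 
180	ha-1	 per hectare 
190	hr-1	 per hour 
200	mol-1	 per mole 
210	ml-1	 per milliliter 
220	l-1	 per liter 
225	d-1	 per day 
228	yr-1	 per year 
230	 cm2	 centimetersquared 
240	 km2	 kilometersquared 
250	 mm2	 millimetersquared 
260	 m2	 metersquared 
270	 m3	 metercubed 
290	metre	meter
295	litre	liter
300	grams 	gram 
310	meters 	meter 
315	liters 	liter 
320	moles 	mole 
325	seconds 	second 
330	minutes 	minute 
335	hours 	hour 
340	days 	day 
345	years 	year 
350	hectares 	hectare 
355	degrees 	degree 
360	kelvins 	kelvin 
365	pascals 	pascal 
370	numbers 	number 
375	counts 	count 
400	per square centimeter	 per centimetersquared 
405	per square meter	 per metersquared 
410	per square kilometer	 per kilometersquared 
412	per square millimeter	 per millimetersquared 
415	per cubic meter	 per metercubed 
425	square centimeter	 centimetersquared 
430	square meter	 metersquared 
435	square kilometer	 kilometersquared 
438	square millimeter	 millimetersquared 
440	cubic meter	 metercubed 
505	 degc 	 degreecelsius 
510	 degf 	 degreefahrenheit 
515	 deg c 	 degreecelsius 
520	 deg f 	 degreefahrenheit 
525	 deg 	 degree 
530	 kg 	 kilogram 
535	 mg 	 milligram 
540	 ug 	 microgram 
545	 gm 	 gram 
550	 g 	 gram 
555	 cm 	 centimeter 
560	 mm 	 millimeter 
565	 um 	 micrometer 
570	 km 	 kilometer 
575	 m 	 meter 
580	 ml 	 milliliter 
585	 ul 	 microliter 
590	 l 	 liter 
595	 sec 	 second 
600	 s 	 second 
605	 min 	 minute 
610	 hr 	 hour 
615	 h 	 hour 
620	 d 	 day 
625	 yr 	 year 
632	 ha 	 hectare 
635	 mmol 	 millimole 
640	 umol 	 micromole 
645	 mol 	 mole 
650	 kpa 	 kilopascal 
655	 hpa 	 hectopascal 
660	 pa 	 pascal 
665	 k 	 kelvin 
670	 ppm 	 partspermillion 
675	 ppt 	 partsperthousand 
680	 per mil 	 permil 
685	 pct 	 percent 
690	 num 	 number 
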