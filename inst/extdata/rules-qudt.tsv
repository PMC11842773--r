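# Default qudt-phase substitution rules.
# Applied, in order, to a pseudounit (lowercase, dash-free). Replacements
# are dash-delimited QUDT-cased tokens, so converted segments are visibly
# distinct from not-yet-converted lowercase text. Longer fragments are
# ordered before the shorter fragments they contain (e.g. centimetersquared
# before percent, kilogram before gram); 'per' is rewritten last.
# Tab-separated: order, pattern, replacement.
order	pattern	replacement
10	kilometersquared	-KiloM2-
15	centimetersquared	-CentiM2-
20	millimetersquared	-MilliM2-
25	metersquared	-M2-
30	metercubed	-M3-
35	squarekilometers	-KiloM2-
40	squarekilometer	-KiloM2-
45	squarecentimeters	-CentiM2-
50	squarecentimeter	-CentiM2-
55	squaremeters	-M2-
60	squaremeter	-M2-
65	cubicmeters	-M3-
70	cubicmeter	-M3-
75	cubitmeter	-M3-
80	kilometers	-KiloM-
85	kilometer	-KiloM-
90	centimeters	-CentiM-
95	centimeter	-CentiM-
100	cenimeter	-CentiM-
105	millimeters	-MilliM-
110	millimeter	-MilliM-
115	micrometers	-MicroM-
120	micrometer	-MicroM-
125	meters	-M-
130	meter	-M-
135	seconds	-SEC-
140	second	-SEC-
145	minutes	-MIN-
150	minute	-MIN-
155	hours	-HR-
160	hour	-HR-
165	days	-DAY-
170	day	-DAY-
175	years	-YR-
180	year	-YR-
185	kilograms	-KiloGM-
190	kilogram	-KiloGM-
195	milligrams	-MilliGM-
200	milligram	-MilliGM-
205	micrograms	-MicroGM-
210	microgram	-MicroGM-
215	grams	-GM-
220	gram	-GM-
225	milliliters	-MilliL-
230	milliliter	-MilliL-
235	microliters	-MicroL-
240	microliter	-MicroL-
245	liters	-L-
250	liter	-L-
255	millimoles	-MilliMOL-
260	millimole	-MilliMOL-
265	micromoles	-MicroMOL-
270	micromole	-MicroMOL-
275	moles	-MOL-
280	mole	-MOL-
285	degreescelsius	-DEG_C-
290	degreecelsius	-DEG_C-
295	degreescelcius	-DEG_C-
300	degreecelcius	-DEG_C-
305	degreesfahrenheit	-DEG_F-
310	degreefahrenheit	-DEG_F-
315	celsius	-DEG_C-
320	celcius	-DEG_C-
325	fahrenheit	-DEG_F-
330	kelvins	-K-
335	kelvin	-K-
340	kilopascals	-KiloPA-
345	kilopascal	-KiloPA-
350	hectopascals	-HectoPA-
355	hectopascal	-HectoPA-
360	pascals	-PA-
365	pascal	-PA-
370	hectares	-HA-
375	hectare	-HA-
380	joules	-J-
385	joule	-J-
390	watts	-W-
395	watt	-W-
400	dimensionless	-UNITLESS-
405	unitless	-UNITLESS-
410	partspermillion	-PPM-
415	partsperthousand	-PPTH-
420	percentage	-PERCENT-
425	percent	-PERCENT-
428	permille	-PPTH-
430	permil	-PPTH-
440	numbers	-NUM-
445	number	-NUM-
450	counts	-NUM-
455	count	-NUM-
460	degrees	-DEG-
465	degree	-DEG-
470	cm2	-CentiM2-
475	km2	-KiloM2-
480	m2	-M2-
485	m3	-M3-
490	mmol	-MilliMOL-
495	umol	-MicroMOL-
500	mol	-MOL-
505	kpa	-KiloPA-
510	hpa	-HectoPA-
515	kg	-KiloGM-
520	mg	-MilliGM-
525	ug	-MicroGM-
530	sec	-SEC-
535	min	-MIN-
540	ppm	-PPM-
545	ppt	-PPTH-
550	hr	-HR-
555	yr	-YR-
560	reciprocal	-PER-
565	per	-PER-
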