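# Subset of the QUDT units vocabulary, v2.1.25 (http://qudt.org/vocab/unit/).
# Codes, URIs, dimension vectors, SI conversion multipliers/offsets and UCUM
# aliases transcribed from the published v2.1.25 release files.
# Columns are tab-separated; multi-valued cells use ";".
code	uri	label	dimension_vector	si_multiplier	si_offset	ucum	quantity_kinds	description
M	http://qudt.org/vocab/unit/M	metre	A0E0L1I0M0H0T0D0	1	0	m	Length	SI base unit of length
CentiM	http://qudt.org/vocab/unit/CentiM	centimetre	A0E0L1I0M0H0T0D0	0.01	0	cm	Length	0.01-fold of the metre
MilliM	http://qudt.org/vocab/unit/MilliM	millimetre	A0E0L1I0M0H0T0D0	0.001	0	mm	Length	0.001-fold of the metre
MicroM	http://qudt.org/vocab/unit/MicroM	micrometre	A0E0L1I0M0H0T0D0	1e-06	0	um	Length	0.000001-fold of the metre
KiloM	http://qudt.org/vocab/unit/KiloM	kilometre	A0E0L1I0M0H0T0D0	1000	0	km	Length	1000-fold of the metre
M2	http://qudt.org/vocab/unit/M2	square metre	A0E0L2I0M0H0T0D0	1	0	m2	Area	SI derived unit of area
CentiM2	http://qudt.org/vocab/unit/CentiM2	square centimetre	A0E0L2I0M0H0T0D0	0.0001	0	cm2	Area
KiloM2	http://qudt.org/vocab/unit/KiloM2	square kilometre	A0E0L2I0M0H0T0D0	1000000	0	km2	Area
HA	http://qudt.org/vocab/unit/HA	hectare	A0E0L2I0M0H0T0D0	10000	0	har	Area	non-SI area unit, 10000 square metres
M3	http://qudt.org/vocab/unit/M3	cubic metre	A0E0L3I0M0H0T0D0	1	0	m3	Volume	SI derived unit of volume
L	http://qudt.org/vocab/unit/L	litre	A0E0L3I0M0H0T0D0	0.001	0	L;l	Volume	non-SI volume unit, 0.001 cubic metre
MilliL	http://qudt.org/vocab/unit/MilliL	millilitre	A0E0L3I0M0H0T0D0	1e-06	0	mL;ml	Volume
MicroL	http://qudt.org/vocab/unit/MicroL	microlitre	A0E0L3I0M0H0T0D0	1e-09	0	uL	Volume
KiloGM	http://qudt.org/vocab/unit/KiloGM	kilogram	A0E0L0I0M1H0T0D0	1	0	kg	Mass	SI base unit of mass
GM	http://qudt.org/vocab/unit/GM	gram	A0E0L0I0M1H0T0D0	0.001	0	g	Mass	0.001-fold of the kilogram
MilliGM	http://qudt.org/vocab/unit/MilliGM	milligram	A0E0L0I0M1H0T0D0	1e-06	0	mg	Mass
MicroGM	http://qudt.org/vocab/unit/MicroGM	microgram	A0E0L0I0M1H0T0D0	1e-09	0	ug	Mass
SEC	http://qudt.org/vocab/unit/SEC	second	A0E0L0I0M0H0T1D0	1	0	s	Time	SI base unit of time
MIN	http://qudt.org/vocab/unit/MIN	minute	A0E0L0I0M0H0T1D0	60	0	min	Time
HR	http://qudt.org/vocab/unit/HR	hour	A0E0L0I0M0H0T1D0	3600	0	h	Time
DAY	http://qudt.org/vocab/unit/DAY	day	A0E0L0I0M0H0T1D0	86400	0	d	Time
YR	http://qudt.org/vocab/unit/YR	year	A0E0L0I0M0H0T1D0	31556952	0	a	Time	mean Gregorian year
K	http://qudt.org/vocab/unit/K	kelvin	A0E0L0I0M0H1T0D0	1	0	K	ThermodynamicTemperature	SI base unit of thermodynamic temperature
DEG_C	http://qudt.org/vocab/unit/DEG_C	degree Celsius	A0E0L0I0M0H1T0D0	1	273.15	Cel	Temperature	affine temperature unit offset 273.15 K
DEG_F	http://qudt.org/vocab/unit/DEG_F	degree Fahrenheit	A0E0L0I0M0H1T0D0	0.5555555555555556	255.3722222222222	[degF]	Temperature
UNITLESS	http://qudt.org/vocab/unit/UNITLESS	unitless	A0E0L0I0M0H0T0D1	1	0		Dimensionless	explicitly dimensionless quantity
NUM	http://qudt.org/vocab/unit/NUM	number	A0E0L0I0M0H0T0D1	1	0	{#}	Dimensionless	a count
PERCENT	http://qudt.org/vocab/unit/PERCENT	percent	A0E0L0I0M0H0T0D1	0.01	0	%	DimensionlessRatio	parts per hundred
PPM	http://qudt.org/vocab/unit/PPM	parts per million	A0E0L0I0M0H0T0D1	1e-06	0	[ppm]	DimensionlessRatio
PPTH	http://qudt.org/vocab/unit/PPTH	parts per thousand	A0E0L0I0M0H0T0D1	0.001	0	[ppth]	DimensionlessRatio	per mille
DEG	http://qudt.org/vocab/unit/DEG	degree	A0E0L0I0M0H0T0D1	0.0174532925199433	0	deg	PlaneAngle	plane angle, pi/180 radian
MOL	http://qudt.org/vocab/unit/MOL	mole	A1E0L0I0M0H0T0D0	1	0	mol	AmountOfSubstance	SI base unit of amount of substance
MilliMOL	http://qudt.org/vocab/unit/MilliMOL	millimole	A1E0L0I0M0H0T0D0	0.001	0	mmol	AmountOfSubstance
MicroMOL	http://qudt.org/vocab/unit/MicroMOL	micromole	A1E0L0I0M0H0T0D0	1e-06	0	umol	AmountOfSubstance
PA	http://qudt.org/vocab/unit/PA	pascal	A0E0L-1I0M1H0T-2D0	1	0	Pa	Pressure	SI derived unit of pressure
KiloPA	http://qudt.org/vocab/unit/KiloPA	kilopascal	A0E0L-1I0M1H0T-2D0	1000	0	kPa	Pressure
HectoPA	http://qudt.org/vocab/unit/HectoPA	hectopascal	A0E0L-1I0M1H0T-2D0	100	0	hPa	Pressure
J	http://qudt.org/vocab/unit/J	joule	A0E0L2I0M1H0T-2D0	1	0	J	Energy	SI derived unit of energy
W	http://qudt.org/vocab/unit/W	watt	A0E0L2I0M1H0T-3D0	1	0	W	Power	SI derived unit of power
GM-PER-M2	http://qudt.org/vocab/unit/GM-PER-M2	gram per square metre	A0E0L-2I0M1H0T0D0	0.001	0	g/m2	MassPerArea
KiloGM-PER-HA	http://qudt.org/vocab/unit/KiloGM-PER-HA	kilogram per hectare	A0E0L-2I0M1H0T0D0	0.0001	0	kg/har	MassPerArea
GM-PER-CentiM2	http://qudt.org/vocab/unit/GM-PER-CentiM2	gram per square centimetre	A0E0L-2I0M1H0T0D0	10	0	g/cm2	MassPerArea
GM-PER-M2-DAY	http://qudt.org/vocab/unit/GM-PER-M2-DAY	gram per square metre per day	A0E0L-2I0M1H0T-1D0	1.1574074074074074e-08	0	g/(m2.d)	MassPerAreaTime
GM-PER-M3	http://qudt.org/vocab/unit/GM-PER-M3	gram per cubic metre	A0E0L-3I0M1H0T0D0	0.001	0	g/m3	MassDensity
GM-PER-L	http://qudt.org/vocab/unit/GM-PER-L	gram per litre	A0E0L-3I0M1H0T0D0	1	0	g/L	MassDensity
MilliGM-PER-L	http://qudt.org/vocab/unit/MilliGM-PER-L	milligram per litre	A0E0L-3I0M1H0T0D0	0.001	0	mg/L	MassDensity
MicroGM-PER-L	http://qudt.org/vocab/unit/MicroGM-PER-L	microgram per litre	A0E0L-3I0M1H0T0D0	1e-06	0	ug/L	MassDensity
MilliMOL-PER-L	http://qudt.org/vocab/unit/MilliMOL-PER-L	millimole per litre	A1E0L-3I0M0H0T0D0	1	0	mmol/L	AmountOfSubstanceConcentration
MicroMOL-PER-L	http://qudt.org/vocab/unit/MicroMOL-PER-L	micromole per litre	A1E0L-3I0M0H0T0D0	0.001	0	umol/L	AmountOfSubstanceConcentration
M-PER-SEC	http://qudt.org/vocab/unit/M-PER-SEC	metre per second	A0E0L1I0M0H0T-1D0	1	0	m/s	LinearVelocity
KiloM-PER-HR	http://qudt.org/vocab/unit/KiloM-PER-HR	kilometre per hour	A0E0L1I0M0H0T-1D0	0.2777777777777778	0	km/h	LinearVelocity
PER-M2	http://qudt.org/vocab/unit/PER-M2	reciprocal square metre	A0E0L-2I0M0H0T0D0	1	0	/m2	InverseArea
MicroMOL-PER-M2-SEC	http://qudt.org/vocab/unit/MicroMOL-PER-M2-SEC	micromole per square metre second	A1E0L-2I0M0H0T-1D0	1e-06	0	umol/(m2.s)	PhotonFlux	photosynthetic photon flux density
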