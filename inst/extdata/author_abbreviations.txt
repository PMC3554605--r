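# Built-in sample of standard botanical author abbreviations
# (abbreviation<TAB>expansion), one per line.
L.	Linnaeus
L.f.	Linnaeus filius
DC.	de Candolle
A.DC.	Alphonse de Candolle
Benth.	Bentham
Hook.	Hooker
Hook.f.	Hooker filius
Kunth	Kunth
Humb.	Humboldt
Bonpl.	Bonpland
Willd.	Willdenow
Lam.	Lamarck
Juss.	Jussieu
A.Juss.	Adrien Jussieu
Mill.	Miller
Desf.	Desfontaines
Pers.	Persoon
Poir.	Poiret
R.Br.	Robert Brown
Sm.	Smith
J.Sm.	John Smith
Sw.	Swartz
Thunb.	Thunberg
Vahl	Vahl
Cav.	Cavanilles
Ruiz	Ruiz
Pav.	Pavon
Aubl.	Aublet
Jacq.	Jacquin
Mart.	Martius
Nees	Nees
Steud.	Steudel
Spreng.	Sprengel
Schltdl.	Schlechtendal
Cham.	Chamisso
Kth.	Kunth
Fisch.	Fischer
C.A.Mey.	Carl Anton Meyer
Ledeb.	Ledebour
Trin.	Trinius
Griseb.	Grisebach
Baker	Baker
Oliv.	Oliver
Engl.	Engler
Diels	Diels
Harms	Harms
Standl.	Standley
A.Gray	Asa Gray
Torr.	Torrey
Nutt.	Nuttall
Michx.	Michaux
Pursh	Pursh
Raf.	Rafinesque
Greene	Greene
Rydb.	Rydberg
Small	Small
Fernald	Fernald
Hitchc.	Hitchcock
Scribn.	Scribner
Urb.	Urban
Radlk.	Radlkofer
Pilg.	Pilger
Ule	Ule
Ducke	Ducke
Spruce	Spruce
Klotzsch	Klotzsch
Poepp.	Poeppig
Endl.	Endlicher
Stapf	Stapf
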