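>mad10_revised revised Mad10 translation (alternative start 15 codons upstream; first 15 aa are the added peptide MSDSVVIIGAGPVGL; original annotation: 467 aa / 1404 nt CDS)
MSDSVVIIGAGPVGLMLAHELALAGVRTVVIERRPEIDARTVSGLIHERSVELLEQRGLM
EQIRREDGEPLVWDRLHFASFWLDMSELAKTDHSVVLLQTRIQRLLSDRAAARGVHILRR
HELVGLSQDEDGVTARVHSPLGEEEIRCGYLVGCDGEDSAVRELAGFAVTRSGPSWYGLL
ADVGSYAGPVGAGSFHEGGMFGQFGDASTMFRLMTIEIGVEAPPAEQPVTLEEVRASIER
ITGERPTVEEPLWLHRHGNVTILADEYRNGRVFLAGDAAHFQFHPAGHAVTIGLQDAVNL
GWKLAAKLQGWAPAGLLDSYDAERRPYGRRACVYGRAQMALLDTADGPSALREVFGELLD
HDVVNRHLVRAATDARYPMGQAEDLVGRRVPLVSLSTPGGEVPVAETLHAARGVLLDLSG
GTEPPDVTGWKDRVDVVAAEPTPEIPASAVLVRPDGHIAWAGEAVGEGLHTALAAWFGEP
AA
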