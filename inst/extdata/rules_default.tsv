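# Default biotransformation catalog for DISS (3,6'-disinapoyl sucrose).
# delta: signed composition change; one sign per rule (pure loss or gain).
name	delta	class
demethylation	-CH2	methylation
methylation	+CH2	methylation
demethoxylation	-CH2O	cleavage
reduction	+H2	reduction
dehydrogenation	-H2	reduction
hydroxylation	+O	oxidation
dehydroxylation	-O	oxidation
hydration	+H2O	hydration
dehydration	-H2O	hydration
sinapoyl ester cleavage	-C11H10O4	cleavage
glycosidic cleavage	-C6H10O5	cleavage
C7H6 loss	-C7H6	cleavage
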