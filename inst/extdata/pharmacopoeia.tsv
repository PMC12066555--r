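term	alias_of
propranolol
metoprolol
bisoprolol
carvedilol
labetalol
felodipine
digoxin
sodium nitroprusside
verapamil
intravenous beta-blockers
intravenous verapamil
ACEI
beta-blockers
ACE inhibitors	ACEI
angiotensin-converting enzyme inhibitors	ACEI
β-receptor blockers	beta-blockers
β-blockers	beta-blockers
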