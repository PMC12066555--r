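mt
beta-blockers
nitrates
new anti-anginal drugs
calcium channel blockers
diuretics
antithrombotic drugs
platelet inhibitors
anticoagulants
fibrinolytic drugs
lipid-regulating and anti-atherosclerotic drugs
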