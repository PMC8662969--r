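# Example XRR model: air | Fe 40 A | Au 60 A | Si, all roughnesses 3 A.
# X-ray slds in 1/Angstrom^2; typical synchrotron resolution/background.
patches:
  - coverage: 1.0
    layers:
      - {sld: 0.0,      isld: 0.0,     thickness: 0,  roughness: 3, solvent: 0, name: air}
      - {sld: 5.94e-5,  isld: 7.7e-6,  thickness: 40, roughness: 3, solvent: 0, name: Fe}
      - {sld: 1.246e-4, isld: 1.31e-5, thickness: 60, roughness: 3, solvent: 0, name: Au}
      - {sld: 2.01e-5,  isld: 4.6e-7,  thickness: 0,  roughness: 0, solvent: 0, name: Si}
instrument:
  resolution: 0.001
  background: 1.0e-9
  scale: 1.0
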