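# Settings mirroring a national-scale wolverine (Gulo gulo) analysis:
# scat-based noninvasive genetic sampling on a 2-km search grid, female
# half-normal scale of about 6 km, AC windows of 5 sigma and detector
# windows extending 2 sigma beyond them. Detector and detection CSVs are
# not bundled; point read_detectors()/read_detections() at the deposited
# monitoring data (unit: km).
spacing: 2            # detector grid resolution, km
buffer: 12            # 2 sigma, km
sigma: 6              # half-normal scale, km
ac_width_sigma: [5]   # AC window 30 km
extension_sigma: [2]  # detector window 54 km
chains: 3
iter: 3000
adapt: 1000
thin: 3
augment_factor: 4
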