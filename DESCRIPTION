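Package: stsca
Title: Spatiotemporal Spike-Centered Averaging for Microelectrode Array Recordings
Version: 0.1.0
Authors@R: person("MEA", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Characterizes the relationship between multi-unit spiking and the
    low-frequency local field potential (LFP) on gridded microelectrode arrays.
    Implements the classical spike-triggered average (STA) and its spatial
    extension, the spatiotemporal spike-centered average (st-SCA), in which each
    spike's whole-array LFP frame is translated so the spike sits at the spatial
    origin before averaging. Includes band-splitting and threshold spike
    detection, plus-minus noise estimation with Rose-criterion masking, ZCA
    spatial whitening, spike-time randomization controls, radial (polar)
    reduction of the st-SCA with ring-geometry quantification, a synthetic MEA
    data generator with known spike-to-LFP kernels, and the rect/sinc
    unit-impulse-response model that links the temporal and spatial components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
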