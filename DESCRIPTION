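Package: librepulse
Title: LIBRE Fat-Suppression Pulse Design and Virtual 3D Radial MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and characterization of lipid-insensitive binomial
    off-resonant excitation (LIBRE) radiofrequency pulses for fat
    suppression in cardiovascular MRI at 3 T. Provides the analytic
    pulse-parameter optimality condition, a Bloch-equation simulator for
    segmented spoiled gradient-echo excitation trains (LIBRE, binomial
    water excitation, and CHESS fat saturation), extraction of
    fat-suppression bandwidths from transverse-magnetization response
    maps, a virtual 3D radial imaging pipeline (spiral phyllotaxis
    trajectory, digital cylinder phantom, k-space synthesis, gridding
    reconstruction, superior-inferior projections), and image-quality
    metrics (SNR, CNR, vessel sharpness and vessel length).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
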