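Package: glosscon
Title: Color and Gloss Constancy Stimuli, Image Metrics, and Observer Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and analysing asymmetric-matching studies of
    color and gloss constancy under image-based lighting. Provides a spectral
    colorimetry core (CIE 1931 integration against equal-energy white,
    non-negative reflectance basis extraction, constrained reflectance
    synthesis for a hue/lightness/chroma stimulus grid, and the Pellacini
    contrast-gloss conversion for the Ward reflection model), equirectangular
    lighting-environment statistics and manipulations (luminance moments,
    diffuseness, spherical-harmonic power spectra, chromatic gamut rotation,
    and phase scrambling with histogram matching), a lightweight
    diffuse-plus-specular renderer over procedural bumpy spheres, simulated
    observers, specular-highlight image metrics (coverage, sharpness, Gaussian
    sub-band RMS contrast, object-region color statistics), and the evaluation
    statistics used to relate image metrics to observer settings (noise
    ceilings, circular and partial correlations, per-environment slopes, and
    leave-one-observer-out regression).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
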