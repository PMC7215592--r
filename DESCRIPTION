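Package: twodes
Title: Analysis of Two-Dimensional Electronic Spectroscopy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the kinetic and coherence analysis of absorptive
    two-dimensional electronic spectroscopy (2DES) data. Provides a container
    for stacks of excitation-emission frequency maps versus population time,
    multi-exponential global fitting by variable projection yielding
    two-dimensional decay-associated spectra (2D-DAS), center-line-slope (CLS)
    analysis of spectral diffusion, Fourier spectra of coherences (FSC) with
    beat maps and peak picking, a synthetic-data generator emulating the
    photophysics of chlorophyll-type chromophores at room temperature and
    77 K, HDF5 serialization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    rhdf5,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
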