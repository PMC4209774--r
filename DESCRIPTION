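Package: voxtex
Title: Three-Dimensional Texture Features and Discriminant Grading for
    Volumetric Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for grading volumetric fluorescence microscopy data by
    three-dimensional texture analysis.  Image stacks are denoised by
    slice-wise bilateral filtering, then summarised by two families of 3D
    texture descriptors: twelve Haralick-style statistics of a gray-level
    co-occurrence matrix averaged over the 13 non-redundant voxel
    displacement directions, and energy/entropy of the eight octant
    subbands of a level-1 separable 3D wavelet transform (Haar and
    Daubechies-2 bases, realised as a per-slice 2D transform followed by a
    1D transform along the stack axis).  Feature selection by
    Wilks'-lambda stepwise discriminant analysis or correlation-matrix
    principal components feeds a pooled-covariance linear discriminant
    classifier that assigns one of four tumor grades.  A seedable
    generator of nucleus-like blob textures provides synthetic four-grade
    cohorts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
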