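Package: combscan
Title: Computational Geometry Toolkit for Honey Bee Comb Micro-CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the architecture of Apis mellifera
    honey comb from volumetric (micro-CT style) grayscale image stacks.
    Maintains three linked representations of a scanned comb (a normalized
    density voxel grid, a signed distance field, and a triangle surface
    mesh) and provides morphological and Boolean operators on signed
    distance volumes, principal/Gaussian/mean curvature estimation by
    bee-scale local quadric fitting, density-weighted geodesic distance
    fields with build-direction inference, Laplacian (Fiedler vector)
    segmentation and isocontour curve skeletons, cell extraction with
    per-cell principal-component frames for tilt and gravity
    reconstruction, attenuation-to-density material quantification, and a
    heuristic reconstruction of comb build order. A deterministic
    synthetic comb-phantom generator with full ground truth supports
    validation of every tool.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    tiff,
    RNifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
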