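Package: vertebend
Title: Automated Digital Bending of Intervertebral Joints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates osteological range of motion (oROM) of intervertebral
    joints from bone-only 3D models by automated digital bending. A motion
    segment (two vertebral meshes, a joint coordinate frame, and ten anatomical
    landmarks) is bent in half-degree increments in six directions until a
    constraint on motion is reached: bony intersection measured by mesh boolean
    overlap, zygapophyseal strain, or centrum strain. Includes a factorial
    sensitivity analysis over joint spacing, intersection threshold, and strain
    bounds; a morphometric joint stiffness proxy; and a synthetic motion-segment
    generator with analytically known geometry for testing without CT data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
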