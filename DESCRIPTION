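Package: maxunet
Title: Multi-Axis Attention U-Net for Medical Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Encoder-decoder network for 2D medical image segmentation built
    from multi-axis self-attention: local windowed (block) attention and
    sparse global (grid) attention with relative positional bias, combined
    with inverted-bottleneck convolutions (MBConv) for downsampling and
    attention-gated skip connections, including a multi-scale channel/spatial
    gate that draws its channel weights from the deeper encoder stage and its
    spatial weights from the shallower one. Includes a pure-R reverse-mode
    automatic differentiation engine, an AdamW training loop with a combined
    cross-entropy and soft-Dice loss, segmentation metrics (Dice, IoU and
    95th-percentile Hausdorff distance via an exact Euclidean distance
    transform), a seeded synthetic-data generator emulating multi-organ label
    maps, PNG/NIfTI dataset handling and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    optparse,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
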