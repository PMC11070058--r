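SUkqAAgAAAAOAAABBAABAAAACwAAAAEBBAABAAAACQAAAAIBAwABAAAAEAAAAAMBAwABAAAAAQAAAAYBAwABAAAAAQAAAA4BAgAWAAAAtgAAABEBBAABAAAAAAEAABUBAwABAAAAAQAAABYBBAABAAAACQAAABcBBAABAAAAxgAAABoBBQABAAAA3AAAABsBBQABAAAA5AAAACgBAwABAAAAAQAAADEBAgAMAAAA7AAAAIwCAAB7InNoYXBlIjogWzIsIDksIDExXX0AAAAAAAAAAAAAAAAAAAAAAAEAAAABAAAAAQAAAAEAAAB0aWZmZmlsZS5weQAAAAAAAAAAAAAABwAOABUAHAAjACoAMQA4AD8ARgAfACYALQA0ADsAQgBJAFAAVwBeAGUAPgBFAEwAUwBaAGEAaABvAHYAfQCEAF0AZABrAHIAeQCAAIcAjgCVAJwAowB8AIMAigCRAJgAnwCmAK0AtAC7AMIAmwCiAKkAsAC3AL4AxQDMANMA2gDhALoAwQDIAM8A1gDdAOQA6wDyAPkAAAHZAOAA5wDuAPUA/AADAQoBEQEYAR8B+AD/AAYBDQEUARsBIgEpATABNwE+AQ0AFAAbACIAKQAwADcAPgBFAEwAUwAsADMAOgBBAEgATwBWAF0AZABrAHIASwBSAFkAYABnAG4AdQB8AIMAigCRAGoAcQB4AH8AhgCNAJQAmwCiAKkAsACJAJAAlwCeAKUArACzALoAwQDIAM8AqACvALYAvQDEAMsA0gDZAOAA5wDuAMcAzgDVANwA4wDqAPEA+AD/AAYBDQHmAO0A9AD7AAIBCQEQARcBHgElASwBBQEMARMBGgEhASgBLwE2AT0BRAFLAQwAAAEEAAEAAAALAAAAAQEEAAEAAAAJAAAAAgEDAAEAAAAQAAAAAwEDAAEAAAABAAAABgEDAAEAAAABAAAAEQEEAAEAAADGAQAAFQEDAAEAAAABAAAAFgEEAAEAAAAJAAAAFwEEAAEAAADGAAAAGgEFAAEAAAAiAwAAGwEFAAEAAAAqAwAAKAEDAAEAAAABAAAAAAAAAAEAAAABAAAAAQAAAAEAAAA=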