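>RPL39 mouse ribosomal protein L39 (51 aa)
MSSHKTFRIKRFLAKKQKQNRPIPQWIRMKTGNKIRYNSKRRHWRRTKLGL
>RPL39L mouse ribosomal protein L39-like (51 aa)
MASHKTFRIKRFLAKKQKQNRPIPQWIQMKTGNKIMYNSKRRHWRRTKLGL
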